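family,site,expected,mean,lo,hi,sd
Calliphoridae,CA90,25,28.73,27.96,30.59,0.55
Calliphoridae,CA72,35,38.21,37.52,39.37,0.49
Calliphoridae,CA168,45,48.59,47.80,49.17,0.40
Calliphoridae,CA261,55,57.79,56.93,58.47,0.35
Calliphoridae,CA252,65,67.66,66.73,68.32,0.36
Calliphoridae,CA243,75,78.61,76.68,79.21,0.39
Sarcophagidae,SA1491,26,30.51,29.02,31.25,0.85
Sarcophagidae,SA1488,36,40.76,39.69,41.53,0.63
Sarcophagidae,SA1479,46,50.17,49.84,50.69,0.18
Sarcophagidae,SA1485,56,59.25,57.57,60.04,0.82
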