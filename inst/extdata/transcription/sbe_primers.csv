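family,site,sequence,size,concentration,role
Calliphoridae,CA90,CTTGATCNGGAATARTHGGAACTTC,25,0.80,universal
Calliphoridae,CA90,CTTGATCCGGTATAATYGGAACTTC,25,0.01,low-signal-alternate
Calliphoridae,CA90,CTTGATCAGGAATAATTGGTACTTC,25,0.20,low-signal-alternate
Calliphoridae,CA72,TTTTTTACTTTATAYTTTATTTTTGGAGCTTGATC,35,0.04,universal
Calliphoridae,CA72,TTTTTTACTTTATATTTYATTTTCGGAGCTTGATC,35,0.06,low-signal-alternate
Calliphoridae,CA168,TTTTTTTTTTTTTTTTGGAGAYGAYCAAATTTATAATGTAATTGT,45,0.10,universal
Calliphoridae,CA261,TTTTTTTTTTTTTTTTTTTTTTTTTTAATTGATTAGTTCCWTTAATACTAGGRGC,55,0.20,universal
Calliphoridae,CA261,TTTTTTTTTTTTTTTTTTTTTTTTTTAATTGAYTAGTTCCTTTAATGTTAGGAGC,55,0.10,low-signal-alternate
Calliphoridae,CA261,TTTTTTTTTTTTTTTTTTTTTTTTTTAATTGATTAGTYCCTTTAATATTAGGAGC,55,0.13,low-signal-alternate
Calliphoridae,CA252,TTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTGGAGGRTTTGGAAATTGAYTAGTYCCWTTAAT,65,0.14,universal
Calliphoridae,CA243,TTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTGGAGGRTTYGGWAATTGAYTAGT,75,1.80,universal
Sarcophagidae,SA1491,AATTCAGAATAACTATGTTCAGCTGG,26,0.06,universal
Sarcophagidae,SA1488,TTTTTTTTTTTTTGAATAACTATGTTCAGCTGGHGG,36,0.15,universal
Sarcophagidae,SA1479,TTTTTTTTTTTTTTTTTTAACTATGTTCAGCTGGHGGDGTRTTTTG,46,0.30,universal
Sarcophagidae,SA1485,TTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTCTATGTTCAGCTGGHGGDGT,56,0.40,universal
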