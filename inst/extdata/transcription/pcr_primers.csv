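family,name,sequence,binding,span_start,span_end
Calliphoridae,CA-SNP-F,CAGTCTATTGCCTAAACTTCAG,tRNA-tyrosine,,
Calliphoridae,CA-SNP-R,GTTARTGCRGGRGGTAAAAGTCA,301-323 on COI,301,323
Sarcophagidae,SA-SNP-F,AAGTTTAGYATCHCAACGWCAAGT,1416-1439 on COI,1416,1439
Sarcophagidae,SA-SNP-R,TTAAACCCATTGCACTAATCTGCC,1543-1566 on COI,1543,1566
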