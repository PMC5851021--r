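schema_version: 1
name: SA
family: Sarcophagidae
pcr:
  forward:
    name: SA-SNP-F
    seq: AAGTTTAGYATCHCAACGWCAAGT
    binding: 1416-1439 on COI
    span: [1416, 1439]
  reverse:
    name: SA-SNP-R
    seq: TTAAACCCATTGCACTAATCTGCC
    binding: 1543-1566 on COI
    span: [1543, 1566]
  amplicon_length: 151
sites:
- label: SA1491
  position: 1491
  direction: reverse
  expected_size: 26
  observed_mean: 30.51
  observed_range: [29.02, 31.25]
  observed_sd: 0.85
- label: SA1488
  position: 1488
  direction: reverse
  expected_size: 36
  observed_mean: 40.76
  observed_range: [39.69, 41.53]
  observed_sd: 0.63
- label: SA1479
  position: 1479
  direction: reverse
  expected_size: 46
  observed_mean: 50.17
  observed_range: [49.84, 50.69]
  observed_sd: 0.18
- label: SA1485
  position: 1485
  direction: reverse
  expected_size: 56
  observed_mean: 59.25
  observed_range: [57.57, 60.04]
  observed_sd: 0.82
sbe_primers:
- site: SA1491
  seq: AATTCAGAATAACTATGTTCAGCTGG
  tail_len: 0
  role: universal
  concentration: 0.06
- site: SA1488
  seq: TTTTTTTTTTTTTGAATAACTATGTTCAGCTGGHGG
  tail_len: 13
  role: universal
  concentration: 0.15
- site: SA1479
  seq: TTTTTTTTTTTTTTTTTTAACTATGTTCAGCTGGHGGDGTRTTTTG
  tail_len: 18
  role: universal
  concentration: 0.30
- site: SA1485
  seq: TTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTCTATGTTCAGCTGGHGGDGT
  tail_len: 36
  role: universal
  concentration: 0.40
genotypes:
  Parasarcophaga albiceps: TATA
  Sarcophaga similis: TAAA
  Sarcophaga haemorrhoidalis: TTAA
  Sarcophaga peregrina: TGAA
  Sarcophaga melanura: CAAA
  Sarcophaga crassipalpis: CAAG
  Sarcophaga dux: AGAA
species_metadata:
  Parasarcophaga albiceps: {authority: "Meigen, 1826"}
  Sarcophaga similis: {authority: "Meade, 1876"}
  Sarcophaga haemorrhoidalis:
    authority: "Fallén, 1817"
    synonym: "Sarcophaga africa (Wiedemann, 1824)"
  Sarcophaga peregrina: {authority: "Robineau-Desvoidy, 1830"}
  Sarcophaga melanura: {authority: "Meigen, 1826"}
  Sarcophaga crassipalpis: {authority: "Macquart, 1839"}
  Sarcophaga dux:
    authority: "Thomson, 1869"
    synonym_note: "revised name of Sarcophaga harpax"
notes: >-
  Four reverse-direction SNP sites near the end of COI distinguish the 7
  Sarcophagidae species; every one of the four is essential (any
  three-site subset collides at least one species pair). Genotype bases
  are detection-channel bases, i.e. the complement of the sense strand
  (reverse-direction extension). The 151-bp amplicon follows from the
  primer spans 1416-1439 and 1543-1566. Observed peak statistics from
  capillary runs (n = 69 specimens).
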