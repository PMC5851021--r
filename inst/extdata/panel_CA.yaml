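schema_version: 1
name: CA
family: Calliphoridae
pcr:
  forward:
    name: CA-SNP-F
    seq: CAGTCTATTGCCTAAACTTCAG
    binding: tRNA-tyrosine
    span: ~
  reverse:
    name: CA-SNP-R
    seq: GTTARTGCRGGRGGTAAAAGTCA
    binding: 301-323 on COI
    span: [301, 323]
  amplicon_length: ~
  amplicon_note: >-
    approximately 353 bp observed on gel; not derivable from coordinates
    because the forward primer binds tRNA-tyrosine, outside the numbered
    COI region
sites:
- label: CA90
  position: 90
  direction: forward
  expected_size: 25
  observed_mean: 28.73
  observed_range: [27.96, 30.59]
  observed_sd: 0.55
- label: CA72
  position: 72
  direction: forward
  expected_size: 35
  observed_mean: 38.21
  observed_range: [37.52, 39.37]
  observed_sd: 0.49
- label: CA168
  position: 168
  direction: forward
  expected_size: 45
  observed_mean: 48.59
  observed_range: [47.80, 49.17]
  observed_sd: 0.40
- label: CA261
  position: 261
  direction: forward
  expected_size: 55
  observed_mean: 57.79
  observed_range: [56.93, 58.47]
  observed_sd: 0.35
- label: CA252
  position: 252
  direction: forward
  expected_size: 65
  observed_mean: 67.66
  observed_range: [66.73, 68.32]
  observed_sd: 0.36
- label: CA243
  position: 243
  direction: forward
  expected_size: 75
  observed_mean: 78.61
  observed_range: [76.68, 79.21]
  observed_sd: 0.39
sbe_primers:
- site: CA90
  seq: CTTGATCNGGAATARTHGGAACTTC
  tail_len: 0
  role: universal
  concentration: 0.80
- site: CA90
  seq: CTTGATCCGGTATAATYGGAACTTC
  tail_len: 0
  role: low-signal-alternate
  concentration: 0.01
- site: CA90
  seq: CTTGATCAGGAATAATTGGTACTTC
  tail_len: 0
  role: low-signal-alternate
  concentration: 0.20
- site: CA72
  seq: TTTTTTACTTTATAYTTTATTTTTGGAGCTTGATC
  tail_len: 6
  role: universal
  concentration: 0.04
- site: CA72
  seq: TTTTTTACTTTATATTTYATTTTCGGAGCTTGATC
  tail_len: 6
  role: low-signal-alternate
  concentration: 0.06
- site: CA168
  seq: TTTTTTTTTTTTTTTTGGAGAYGAYCAAATTTATAATGTAATTGT
  tail_len: 16
  role: universal
  concentration: 0.10
- site: CA261
  seq: TTTTTTTTTTTTTTTTTTTTTTTTTTAATTGATTAGTTCCWTTAATACTAGGRGC
  tail_len: 26
  role: universal
  concentration: 0.20
- site: CA261
  seq: TTTTTTTTTTTTTTTTTTTTTTTTTTAATTGAYTAGTTCCTTTAATGTTAGGAGC
  tail_len: 26
  role: low-signal-alternate
  concentration: 0.10
- site: CA261
  seq: TTTTTTTTTTTTTTTTTTTTTTTTTTAATTGATTAGTYCCTTTAATATTAGGAGC
  tail_len: 26
  role: low-signal-alternate
  concentration: 0.13
- site: CA252
  seq: TTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTGGAGGRTTTGGAAATTGAYTAGTYCCWTTAAT
  tail_len: 33
  role: universal
  concentration: 0.14
- site: CA243
  seq: TTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTTGGAGGRTTYGGWAATTGAYTAGT
  tail_len: 52
  role: universal
  concentration: 1.80
genotypes:
  Lucilia ampullacea: ACTCGT
  Lucilia caesar: ACTCAT
  Lucilia illustris: ACTTAT
  Chrysomya megacephala: ACATGT
  Chrysomya pinguis: ACATAT
  Triceratopyga calliphoroides: AATTAC
  Calliphora lata: AATTAT
  Phormia regina: ATAAAT
  Calliphora vicina: AGTTAC
  Lucilia sericata: TCTTAT
  Aldrichina grahami: TACCAC
species_metadata:
  Lucilia ampullacea: {authority: "Villeneuve, 1922"}
  Lucilia caesar: {authority: "Linnaeus, 1758"}
  Lucilia illustris: {authority: "Meigen, 1826"}
  Chrysomya megacephala: {authority: "Fabricius, 1794"}
  Chrysomya pinguis: {authority: "Walker, 1858"}
  Triceratopyga calliphoroides: {authority: "Rohdendorf, 1931"}
  Calliphora lata: {authority: "Coquillett, 1898"}
  Phormia regina: {authority: "Meigen, 1826"}
  Calliphora vicina: {authority: "Robineau-Desvoidy, 1830"}
  Lucilia sericata: {authority: "Meigen, 1826"}
  Aldrichina grahami: {authority: "Aldrich, 1930"}
notes: >-
  Six forward-direction SNP sites on the front section of COI distinguish
  the 11 Calliphoridae species. Eleven SBE primers: 6 universal, 5
  low-signal alternates. Dye colours follow the SNaPshot chemistry
  (A=green/dR6G, C=black/dTAMRA, G=blue/dR110, T=red/dROX) and are derived
  from the genotype bases rather than stored. Genotype bases are
  detection-channel bases (for forward sites, identical to the sense
  strand). Observed peak statistics are from capillary runs on an ABI 3500
  with GeneScan-120 LIZ sizing (n = 116 specimens).
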