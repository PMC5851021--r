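Package: snapanel
Title: SNP Panel Design and SNaPshot Genotype Calling for Fly Species
    Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for molecular identification of forensically important
    blow flies (Calliphoridae) and flesh flies (Sarcophagidae) from
    species-specific SNPs on the mitochondrial COI barcode. Builds IUPAC
    consensus sequences from per-species alignments, discovers interspecific
    SNP candidate sites, selects a minimal discriminating site combination
    (exact branch-and-bound or greedy set cover), designs single-base
    extension (SBE) primers with poly-T size ladders for SNaPshot multiplex
    assays, and calls species either in silico from query sequences or from
    capillary-electrophoresis peak tables (dye colour, size, height). Ships
    two validated reference panels covering 11 Calliphoridae and 7
    Sarcophagidae species, seeded simulators for synthetic sequences and
    noisy peak profiles, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
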