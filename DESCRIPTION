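Package: ripcouple
Title: Coupled RNA-Seq and RIP-Seq Analysis of RNA-Binding Protein
    Target Displacement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for quantifying how a small molecule
    displaces transcripts from an RNA-binding protein (RBP) during an
    inflammatory stimulus, from paired RNA-seq and RIP-seq count matrices
    through negative-binomial differential expression and differential
    binding, expression-binding coupling correlations, a gene-filtering
    cascade, kernel-density difference surfaces, AU-rich element (ARE)
    scanning of 3'-UTRs, and bench-assay calculators (RIP-qPCR fold
    enrichment, delta-delta-Ct relative expression, one-site IC50 fits,
    Welch's t-test). Includes a synthetic-data generator with per-gene
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    jsonlite,
    methods,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
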