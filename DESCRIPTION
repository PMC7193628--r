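Package: crisprHDR
Title: Pooled CRISPRi HDR Screen Scoring and Amplicon Editing-Outcome
    Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for fluorescence-reporter pooled CRISPRi
    screens of homology-directed repair (HDR) and for deep-sequenced
    amplicon editing outcomes. Provides guide-cassette read counting
    against a guide library, counts-per-million normalization, sorted
    versus unsorted log2 guide enrichments, gene-level phenotype
    collapse with a non-targeting-control Mann-Whitney null and hit
    calling, cross-screen unity normalization and binning of essential
    gene phenotypes, and an amplicon read classifier (adapter trim,
    pair merging, affine-gap global alignment to reference and donor,
    HDR/NHEJ/mixed calls with cut-site window and donor-flag rules).
    A seeded synthetic-data generator produces screen count matrices
    and amplicon read pools with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
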