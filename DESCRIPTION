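Package: scontact
Title: Single-Cell Hi-C Contact Analysis and ecDNA Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for barcoded single-cell chromatin contact (Hi-C) data.
    Reads 4DN-style pairs files carrying a cell-barcode column, performs
    per-cell quality control, builds per-cell sparse binned contact matrices,
    and infers copy number from contact coverage. Provides per-bin trans-contact
    statistics (Gini "hub index", trans-to-cis contacting-bin ratio), two
    extrachromosomal DNA (ecDNA) callers -- a multivariate logistic regression
    and a small convolutional network over binarized 5 Mb neighbourhood contact
    profiles -- a copy-number-weighted binomial test for significant ecDNA
    trans-interactions, 10 kb ecDNA boundary refinement, multi-way chromatin
    hub calling, chromatin-domain boundary variability tests, and
    chromatin-based cell annotation and tumour-state scoring. A seeded
    synthetic-data generator emulates barcoded per-cell contacts with distance
    decay, ecDNA and HSR amplicons, multi-way walks and matched expression so
    every analysis is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    Matrix,
    stats,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
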