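Package: phenobmc
Title: Phenotype-Anchored Benchmark-Concentration Analysis for
    Concentration-Response Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phenotype-anchored concentration-response analysis of
    developmental toxicity studies: maximum-likelihood fitting of
    three-parameter log-logistic models to dichotomous morphology endpoints
    with extra-risk benchmark concentrations (BMC), Fisher/Holm incidence
    time-course testing, TMM/log2-CPM preprocessing and a negative-binomial
    Wald differential-expression screen for count matrices, per-gene
    continuous dose-response modeling over six model families with AIC
    selection, standard-deviation-based BMCs and bootstrap confidence
    intervals, phenotype anchoring and cross-chemical uniqueness/overlap set
    logic, and kappa-statistic functional-enrichment networks. Includes a
    synthetic-data generator emulating pooled-embryo RNA-seq and 96-well
    morphology plate designs so every stage is testable with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    DESeq2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
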