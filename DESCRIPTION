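Package: nichescape
Title: Spatial Tumor-Immune Microenvironment Analysis for Multiplexed
    Single-Cell Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for segmented single-cell tables from
    multiplexed immunofluorescence imaging of tumor tissue. Provides
    hierarchical two-tier phenotype classification, functional marker
    gating at a fixed false-positive rate, k-nearest-neighbor cellular
    community clustering, index-cell-centric fixed-radius neighborhood
    construction (tumor-centric and cytotoxic-T-centric), homotypic and
    heterotypic interaction scoring, and per-patient cohort comparison
    with chi-squared tests and Benjamini-Hochberg adjustment. Includes a
    synthetic tumor-core tissue generator (Thomas-process tumor nests,
    planted immune attraction, two-component marker intensity models)
    so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    e1071,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
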