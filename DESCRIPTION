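Package: paucpanel
Title: Prognostic Transcript Panels by Partial-AUC Screening and Bootstrap
    Stability Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-cohort pipeline for discovering and validating prognostic
    gene-expression biomarkers of metastatic-lethal prostate cancer.
    Genomewide per-transcript ROC screening ranks transcripts by AUC and by
    partial AUC at 95% specificity; candidates are then selected by forward
    logistic model building over a Gleason-score base model, stabilized across
    bootstrap resamples; robust markers are evaluated in an independent cohort
    with permutation p-values, stratified bootstrap confidence intervals,
    t-tests, Benjamini-Hochberg false discovery rates, and likelihood-ratio
    tests against the Gleason-only model. Includes preprocessing (quantile
    normalization, log2 transform, probe filtering, location-scale batch
    adjustment, replicate quality control), a seeded synthetic two-cohort
    generator with planted effects, table renderers, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    limma,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
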