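Package: gmbayes
Title: Geometric-Mean Naive Bayes Classification of Targeted Transcriptome Panels
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stability-based per-gene selection, a geometric-mean naive
    Bayesian (GMB) classifier under stratified k-fold cross-validation, and
    ROC evaluation with Hanley-McNeil confidence intervals and Youden
    cut-offs, for binary outcome prediction from targeted RNA expression
    panels (FPKM gene-by-sample matrices).  Includes a negative-binomial
    synthetic-cohort generator emulating post-transplant bone-marrow
    profiling studies, readers and writers for the plain-text matrix,
    label and gene-panel formats involved, and an end-to-end analysis
    pipeline with a training/validation split.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
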