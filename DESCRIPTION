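Package: grndyn
Title: Gene Regulatory Network Inference from Time Series and Steady-State
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers gene regulatory networks from time series and
    steady-state expression data with semi-parametric ordinary
    differential equation models whose transcription functions are
    learned as Random forests (the dynGENIE3 framework), alongside the
    static GENIE3 variant and median-corrected knockout z-scores.
    Regulatory links are ranked by normalized Mean Decrease Impurity
    variable-importance scores. Includes trajectory simulation and
    double-knockout prediction from the fitted models, precision-recall
    evaluation against gold-standard edge sets with permutation-based
    significance, out-of-bag prediction and tree-stability diagnostics
    for decay-rate tuning, and a generator of DREAM4-like benchmark
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
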