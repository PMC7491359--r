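Package: rknbayes
Title: Bayesian Model Comparison for Remember-Know-New Recognition Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing remember-know-new (and sure-unsure-new)
    recognition-memory experiments with a 2 x 2 lexicality-by-status design.
    Computes the scaled difference between remember and know responses per
    participant and condition, compares equality- and order-constrained models
    of the condition means with default g-prior Bayes factors (analytic
    quadrature for equality structures, the encompassing approach for
    inequalities), reproduces the classic 2 x 2 repeated-measures ANOVA with
    Greenhouse-Geisser correction and generalized eta squared, and simulates
    trial-level datasets with realistic between-participant response-preference
    heterogeneity for model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
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
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
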