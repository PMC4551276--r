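Package: rocboot
Title: Operational ROC Analysis with Two-Sample Bootstrap Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for operational receiver operating characteristic (ROC)
    analysis of match-score data with discrete, tied score distributions, as
    used in biometric evaluation. Computes the true accept rate at a specified
    false accept rate with proportional tie division, true and false accept
    rates at a given threshold, the equal error rate with its discreteness-
    induced systematic error, the area under the ROC curve as a Mann-Whitney
    statistic, and weighted error costs. Measurement uncertainties (standard
    errors and confidence intervals) are estimated by the nonparametric
    two-sample bootstrap; a Monte Carlo study of bootstrap variability
    calibrates the number of replications via coefficients of variation.
    One-algorithm and two-algorithm Z-tests are provided, with a synchronized
    resampling estimator of the correlation between paired algorithms.
    Includes a synthetic score-sample generator for testing and examples.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
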