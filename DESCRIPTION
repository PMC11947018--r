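Package: calicat
Title: Calibration-Error-Aware Computerized Adaptive Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for computerized adaptive testing (CAT) under
    the two-parameter logistic item response model when item parameters carry
    calibration error. Implements Warm's weighted likelihood estimator (WLE)
    and its measurement-error bias-corrected version (cWLE), maximum Fisher
    information item selection and its Bayesian version (BMI) averaging
    information over parameter draws, and a fully Bayesian sequential CAT
    engine that marginalizes item-parameter uncertainty over stored
    calibration draws while carrying an empirical normal prior forward.
    Includes linked-design item calibration by marginal maximum likelihood
    with bootstrap error estimation, a hierarchical Bayesian 2PL sampler, and
    a Monte Carlo harness for conditional bias and mean squared error of
    ability estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
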