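Package: restdcm
Title: Learning-Induced Changes in Resting-State Effective Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end simulation and inference pipeline for detecting
    consolidation of rapid perceptual learning in resting-state effective
    connectivity between two brain regions. Provides a seeded synthetic-cohort
    generator (exponential learning behavior, bilinear neuronal dynamics with
    balloon-model hemodynamics), inverse-efficiency learning-curve fitting,
    region-of-interest first-level GLMs with parametric learning modulators,
    a 2x2 day-by-time psychophysiological-interaction screen on run-wise
    coupling slopes, and a ten-model space of bilinear dynamic causal models
    inverted with an exact Kalman-filter marginal likelihood and Laplace
    approximation to the log model evidence, compared by fixed-effects
    Bayesian model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
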