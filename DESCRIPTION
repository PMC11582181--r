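Package: ordssm
Title: Graded Response State-Space Models for Ordinal Intensive Longitudinal Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits discrete-time state-space models with VAR(1) latent dynamics
    to ordinal (Likert-type) intensive longitudinal data, such as ecological
    momentary assessment time series, using a graded response (IRT)
    measurement model. The marginal variance of every latent state is fixed
    to one by solving for the innovation variances as a function of the
    transition matrix, so dynamics estimates are comparable across
    measurement models. Estimation is by iterated filtering (MIF2) over a
    bootstrap particle filter, with slice-likelihood approximate standard
    errors and Wald confidence intervals. Includes an exact Kalman filter
    for the linear-Gaussian comparator, a synthetic-data generator for the
    two-state graded-response design, and a simulation-study harness with
    state-recovery, bias and coverage outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
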