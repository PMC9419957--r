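Package: specdcm
Title: Spectral Dynamic Causal Modelling of Diurnal Effects in Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-spectral-density dynamic causal modelling (spectral DCM) of
    small directed networks from resting-state BOLD time series, with
    hierarchical parametric empirical Bayes (PEB), Bayesian model reduction,
    comparison and averaging over an 18-model time-of-day hypothesis space.
    Includes a seeded generative simulator (linear neuronal dynamics, Balloon
    hemodynamics, power-law fluctuations) for multi-subject, multi-session
    cohorts, nuisance regression and ROI eigenvariate extraction, and
    variational-Laplace model inversion in the frequency domain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    purrr,
    tidyr,
    ggplot2,
    rlang,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
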