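Package: pursuitdcm
Title: Active-Inference Modelling and Dynamic Causal Modelling of Smooth-Pursuit Eye Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates Bayes-optimal oculomotor pursuit of a partially occluded,
    sinusoidally moving target using active inference (generalised filtering in
    generalised coordinates of motion), and inverts averaged eye-tracking
    trajectories with a meta-Bayesian dynamic causal model to estimate
    subjective precisions, kinetic couplings and prior beliefs - together with
    their condition-specific changes under a 2 x 2 (motion noise x speed)
    pursuit paradigm. Includes stimulus generation with phase-noise random
    walks, preprocessing of raw eye traces into normalised grand-averaged
    single-cycle trajectories, variational Laplace model inversion,
    Bayesian model reduction and Bayesian model averaging, and a synthetic
    multi-subject cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
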