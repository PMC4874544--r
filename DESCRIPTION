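Package: gaitprc
Title: Phase Response Curve Estimation for Rhythmic Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates phase response curves (PRCs) of rhythmic locomotion from
    perturbation time series. Implements the classical impulse method and the
    weighted spike-triggered average (WSTA) method, including a multi-cycle
    variant with minimum-variation candidate selection, together with
    phase-transition-curve analysis, gait event detection from marker
    trajectories, cycle-structure statistics, and a ground-truth limit-cycle
    gait simulator for validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
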