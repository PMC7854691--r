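Package: trackpace
Title: Optimal-Control Modelling of 10,000 m Track Pacing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates world-class 10,000 m track races as a minimum-time
    optimal control problem over coupled ordinary differential equations for
    instantaneous speed, propulsive force per unit mass and anaerobic energy
    (maximal accumulated oxygen deficit), with a centripetal force constraint
    on the bends of a standard 400 m track. Provides direct-collocation
    transcription and an augmented-Lagrangian solver, 100 m split-time
    computation, tactical speed corridors, calibration of physiological
    parameters to observed split series, counterfactual scenario experiments
    (reduced anaerobic capacity, worse running economy), and a synthetic
    championship-race generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
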