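Package: frailspan
Title: Frailty-Free and Frail Life Expectancies from Multi-State Models of Ageing Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for estimating frailty-free, frail and total life
    expectancies from interval-censored longitudinal panel data. Builds a
    deficit-accumulation frailty index, classifies robust / pre-frail / frail
    states, fits a four-state continuous-time Markov multi-state model with
    covariate-dependent transition intensities by maximum likelihood, and
    converts fitted intensities into state-specific life expectancies with
    parametric-bootstrap confidence intervals. Includes a synthetic ageing
    cohort generator with known ground truth for end-to-end validation, a
    vital-date jittering utility for year-precision birth and death dates,
    and reporting helpers for stratified life-expectancy tables and group
    contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    Matrix,
    nnet,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
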