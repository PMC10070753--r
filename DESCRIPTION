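Package: nalbupop
Title: Population Pharmacokinetics of Nalbuphine During General Anesthesia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonlinear mixed-effects modeling pipeline for intravenous
    nalbuphine in adult surgical patients: a closed-form two-compartment
    disposition model with covariate submodels, first-order conditional
    estimation with eta-epsilon interaction (FOCE-I), stepwise covariate
    selection with objective-function thresholds, model evaluation by
    goodness-of-fit quantities, nonparametric bootstrap,
    prediction-corrected visual predictive checks and external validation
    (MDPE/MAPE/F20/F30), Monte Carlo simulation of covariate effects and
    fixed-dose versus bodyweight-based dosing regimens, and generation of
    synthetic virtual cohorts with the covariate structure of the study
    population.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    pracma,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
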