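Package: piptazpk
Title: Population Pharmacokinetics and PK/PD Target Attainment of
    Piperacillin/Tazobactam in Late Elderly Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear mixed-effects (FOCE) population pharmacokinetic
    modelling and Monte Carlo probability-of-target-attainment (PTA)
    simulation for the 8:1 piperacillin/tazobactam combination in patients
    aged 75 years and older. Provides closed-form one- and two-compartment
    intravenous-infusion kinetics with steady-state superposition, the
    pharmacodynamic metrics fT>MIC and unbound AUC over 24 h, a
    covariate-parameterised population model with Cockcroft-Gault renal
    function, a synthetic-cohort generator emulating the study design,
    FOCE estimation with stepwise covariate selection, bootstrap and
    sampling-importance-resampling uncertainty, conditional weighted
    residual diagnostics, PK/PD breakpoint tables over renal-function
    grids, and joint two-analyte dosing recommendations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma
Config/testthat/edition: 3
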