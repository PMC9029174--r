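Package: pippk
Title: Population Pharmacokinetics and Dosing Simulation of Piperacillin in
    Critical Illness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric population pharmacokinetic modelling of piperacillin
    in critically ill adults: closed-form one- and two-compartment infusion
    kinetics with steady-state initial conditions, an adaptive-grid
    nonparametric population fit with a renal-function covariate on clearance
    and a heteroscedastic residual-error model, Bayesian individual posteriors,
    internal diagnostics (goodness-of-fit regression, visual predictive check,
    normalized prediction distribution errors, Bland-Altman agreement),
    external-validation bias and precision metrics (MPE/RMSPE with confidence
    intervals), and Monte Carlo probability and fractional target attainment
    for fT>MIC dosing targets against MIC distributions. Includes a synthetic
    cohort generator emulating the sparse intensive-care sampling design so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
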