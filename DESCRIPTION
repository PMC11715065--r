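Package: dabipkpd
Title: Pharmacokinetic-Pharmacodynamic Modelling of Dabigatran
    Anticoagulation in Sheep
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Population pharmacokinetic-pharmacodynamic modelling of the
    direct thrombin inhibitor dabigatran and its reversal agent
    idarucizumab in sheep.  Implements a two-compartment disposition model
    with allometric weight scaling, an effect-compartment link to a
    sigmoid Emax model for thromboelastographic reaction time (R-time),
    and an empirical reversal-effect compartment for idarucizumab.
    Provides a virtual-cohort simulator with log-normal between-subject
    variability and combined residual error, nonlinear mixed-effects
    estimation (FOCE with interaction, Laplace, naive pooled) including a
    sequential population-PK-then-PD scheme, prediction-corrected visual
    predictive checks, and target-concentration dose design for a
    cardiopulmonary bypass circuit.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    ggplot2,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
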