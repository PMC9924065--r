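Package: cpg2mtx
Title: Population PK/PD Modelling of Glucarpidase Rescue After High-Dose
    Methotrexate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coupled population pharmacokinetic-pharmacodynamic modelling of
    glucarpidase (carboxypeptidase G2, CPG2) rescue therapy for delayed
    high-dose methotrexate (MTX) excretion.  Provides the one-compartment
    CPG2 infusion model, the two-compartment MTX model with catalyst-driven
    Michaelis-Menten decomposition, simulation of phase-1- and phase-2-like
    study cohorts, FOCE/Laplace-type population estimation with covariate
    screening and stepwise selection, empirical-Bayes (MAP) individual
    estimation, model diagnostics (goodness of fit, nonparametric bootstrap,
    visual predictive check), and limited-sampling-strategy evaluation of
    Bayesian 48-h MTX concentration forecasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
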