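Package: avalpk
Title: Population Pharmacokinetics of Avalglucosidase Alfa with
    Bodyweight-Based Dosing Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Nonlinear mixed-effects pharmacokinetic model for the enzyme
    replacement therapy avalglucosidase alfa: a concatenated three-compartment
    disposition model with parallel linear and Michaelis-Menten elimination,
    time-varying allometric bodyweight scaling and log-normal inter-individual
    variability. Provides stepped-infusion simulation, exposure metrics (Cmax
    and AUC over the two-week dosing interval), virtual pediatric and adult
    cohort generation with bodyweight cut-off dosing scans, maximum a
    posteriori and population parameter estimation with stepwise covariate
    selection, and model-qualification tools (visual predictive checks,
    nonparametric bootstrap, goodness-of-fit metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
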