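Package: chirotktd
Title: Toxicokinetic-Toxicodynamic Modelling of Acute and Chronic
    Insecticide Effects in Chironomus riparius
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to disentangle direct and indirect mechanisms of chronic
    lethality in aquatic insects with toxicokinetic-toxicodynamic (TK-TD)
    models.  Implements the reduced General Unified Threshold model of
    Survival (GUTS-RED) under both the stochastic-death (SD) and the
    individual-tolerance (IT) assumption, with analytic scaled-damage
    kinetics for constant, pulsed and single-first-order declining exposure,
    Bayesian calibration on acute immobility data via a conditional-binomial
    likelihood, EFSA model-performance metrics (PPC, NRMSE, SPPE) and LCx
    computation by bisection.  Couples the calibrated damage dynamics to a
    dynamic energy budget (DEB) model of chironomid larvae in which feeding
    inhibition is the physiological mode of action and starvation the only
    cause of death, so that chronic mortality can emerge indirectly from
    sublethal stress.  Includes seeded generators for synthetic acute and
    chronic datasets matching standard test-guideline designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
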