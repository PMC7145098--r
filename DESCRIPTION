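Package: bfabm
Title: Agent-Based Simulation of Breastfeeding Intent, Initiation and
    Maintenance in a Low-Income Population
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the breastfeeding decisions and experiences of a
    synthetic cohort of low-income (WIC) primiparous women from late
    pregnancy through six months postpartum.  Each woman forms a prenatal
    intent to breastfeed (logistic in her knowledge score, with optional
    homophilous peer influence), decides at childbirth whether to initiate
    (logistic in intent and delivery at a Baby-Friendly hospital), and then
    moves through exclusive / partial / formula feeding states under three
    residual monthly transition rates and two scheduled barriers (lactation
    problems, return to work) resolved by support-dependent decision trees.
    Includes synthetic-population generation from marginal distributions,
    RMSE grid-search calibration of the transition rates, intervention
    coverage scenarios and packages with replicate-averaged outcome
    summaries, synergy measures, and sensitivity sweeps.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
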