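Package: nutrimpact
Title: Nutrition Intervention Impact Modelling in the Lives Saved Tool Style
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open, testable engine for LiST-style estimation of the
    mortality and nutrition impact of scaling up maternal and child
    nutrition interventions in low- and middle-income countries. Ships a
    machine-readable registry of intervention-outcome pairs (efficacies,
    odds ratios, affected fractions, GRADE quality), a modified-GRADE
    evidence scorer, effect-size conversion utilities (relative risk to
    efficacy, odds-ratio shifts of prevalence distributions),
    inverse-variance and DerSimonian-Laird random-effects meta-analysis
    with food-type subgroups, affected-fraction resolution against country
    profiles with a food-insecurity to poverty fallback, and a
    deterministic scenario engine that converts coverage scale-up into
    deaths averted and risk-factor prevalence trajectories. Includes seeded
    synthetic generators for country profiles, trial sets and scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
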