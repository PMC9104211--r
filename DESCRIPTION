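Package: renalcea
Title: Cost-Effectiveness Modelling of Imaging Strategies for Solid Renal Masses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Decision-analytic modelling of the diagnostic workup of solid
    renal masses. A diagnostic decision tree (contrast-enhanced ultrasound,
    computed tomography, magnetic resonance imaging) feeds a four-state
    monthly-cycle Markov cohort model that accrues discounted costs and
    quality-adjusted life years over a lifetime horizon. The package computes
    incremental cost-effectiveness ratios and the dominance frontier,
    deterministic (tornado) and probabilistic (Monte Carlo with
    cost-effectiveness acceptability curves) sensitivity analyses, and ships
    a patient-level microsimulation oracle plus synthetic life-table and
    parameter generators so every analysis runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
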