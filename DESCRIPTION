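Package: inhalrisk
Title: Probabilistic Inhalation Health Risk Assessment for Occupational Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic and probabilistic human-health risk assessment for
    inhaled volatile organic compounds in occupational settings. Implements
    the USEPA chronic daily intake and exposure concentration dose metrics,
    carcinogenic risk (slope-factor) and hazard quotient (reference
    concentration) indices, gas-phase unit conversions and Brief & Scala
    adjustment of occupational exposure limits for extended shifts, reduction
    of personal sorbent-tube sampling records to breathing-zone
    concentrations, Monte Carlo uncertainty propagation with truncated input
    distributions, signed contribution-to-variance sensitivity analysis, and
    a synthetic cohort generator for end-to-end testing without measurement
    data. Ships a worked preset for 1,3-butadiene and styrene exposure in
    carpet-factory finishing shops.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
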