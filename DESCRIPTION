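Package: txavert
Title: Avoidable Trauma Mortality Under Tranexamic Acid Administration Strategies
Version: 0.1.0
Authors@R:
    person("Matthew", "Reed", email = "mreed@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for estimating avoidable trauma
    mortality under alternative prehospital tranexamic acid (TXA)
    administration strategies. Ingests aggregated death-certificate strata
    (CDC WONDER Underlying Cause of Death export dialect) and patient-level
    trauma-registry records (NTDB-style schema), applies cohort
    inclusion/exclusion criteria for a TXA-naive study window, estimates the
    annual burden of bleeding deaths, and propagates CRASH-2 relative-risk
    -reduction confidence bounds through counterfactual deaths-averted
    scenarios, nationally and per state. Includes seeded synthetic-data
    generators for both sources so every stage is testable without
    license-restricted downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
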