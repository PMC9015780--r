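Package: pedtherm
Title: Continuous Plantar Temperature Monitoring and Contralateral
    Differential Analysis
Version: 0.1.0
Authors@R:
    person("Pedtherm", "Maintainers", email = "maintainers@pedtherm.dev",
           role = c("aut", "cre"))
Description: Analysis pipeline for continuous bilateral plantar temperature
    monitoring in patients with peripheral neuropathy at risk of diabetic
    foot injury. Computes per-minute contralateral temperature differentials
    at six plantar sites, aggregates them to daily per-location averages,
    applies the clinical >4 degree Fahrenheit alert rule with sustained
    hotspot escalation, segments records into baseline, pre-injury and
    active-injury periods, extracts 15-day/900-minute analysis windows for
    injury and control cohorts, and performs the cohort comparison with a
    Welch t statistic implemented from formula. A calibrated synthetic
    sensor-stream generator (wear cycles, circadian rhythm, day-level drift,
    sensor noise, injectable injury archetypes) makes every stage testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
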