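Package: copdalert
Title: Personalized Telemonitoring Alert Thresholds for COPD Self-Management
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for daily COPD telemonitoring data: per-patient
    empirical distributions of symptom score, pulse rate and oxygen saturation
    estimated over an initial run-in period; directional 95th-centile alert
    thresholds; alert detection on follow-up days; extraction of exacerbation
    events from medication diaries (patient-initiated antibiotics and/or oral
    steroids); linkage of alerts to events over a pre-event window;
    compliance and application-usage analytics. Includes a seeded synthetic
    cohort generator so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    patchwork,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
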