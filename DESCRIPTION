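Package: markovcea
Title: Markov Cohort Cost-Effectiveness Analysis for Second-Line
    Esophageal Cancer Immunotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-state (progression-free, progressed, dead) Markov cohort
    model for cost-effectiveness analysis of pembrolizumab versus
    chemotherapy as second-line treatment of advanced esophageal cancer,
    with parameter sets for the KEYNOTE-181 trial populations (total
    population, PD-L1 CPS >= 10, squamous cell carcinoma). Provides the
    cohort engine with half-cycle correction and discounting, incremental
    cost-effectiveness ratios, calibration of monthly transition
    probabilities to overall-survival and progression-free-survival
    curves, one-way and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, a synthetic patient-level
    data generator with Kaplan-Meier estimation, and a command-line
    interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
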