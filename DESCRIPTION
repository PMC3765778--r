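Package: metscea
Title: Risk-Stratified Cost-Effectiveness Analysis of Lifestyle Programs
    for the Metabolic Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for health-economic evaluation of primary-care lifestyle
    counselling programs for patients with the metabolic syndrome. Patients
    are stratified into low/medium/high risk groups by counting consensus
    metabolic-syndrome criteria; lifetime cardiovascular disease and type 2
    diabetes outcomes are projected with a Markov microsimulation (annual
    cycles to age 85) under start versus post-intervention risk-factor
    levels; discounted QALYs, costs, ICERs, deterministic scenario analyses
    and a bootstrap probabilistic sensitivity analysis on the
    cost-effectiveness plane are computed. Includes a synthetic-cohort
    generator that emulates published group-level risk-factor tables so the
    full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
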