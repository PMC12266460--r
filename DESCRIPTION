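Package: weightcea
Title: Cost-Effectiveness Analysis of Weight-Loss Maintenance Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Trial-based cost-effectiveness analysis of behavioural
    weight-loss maintenance interventions. Estimates weight-loss-state
    transition matrices from longitudinal participant records, propagates a
    four-state discrete-time Markov cohort model (limited/moderate/large
    weight loss plus an absorbing death state) over a multi-year horizon,
    attaches program delivery costs, state-conditional out-of-pocket costs
    and survey-derived quality-adjusted life years, and computes incremental
    cost-effectiveness ratios with probabilistic (truncated-normal and
    zero-inflated-gamma) and one-way deterministic sensitivity analysis.
    Includes a synthetic trial-cohort generator so every pipeline stage is
    testable without participant-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    fitdistrplus,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
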