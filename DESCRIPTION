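Package: cvdscreen
Title: Cost-Effectiveness Modelling of Cardiovascular Risk Screening Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modelling pipeline for evaluating the cost-effectiveness of
    population cardiovascular disease (CVD) risk screening program designs in
    low-resource health systems. Generates seedable synthetic adult cohorts
    with realistic joint risk-factor structure, scores 10-year CHD and stroke
    risk with configurable equation- and chart-based tools, applies screening
    and treatment policies (risk thresholds, age rules, statins for diabetics,
    lowered blood-pressure thresholds), propagates each screened individual
    through a five-state lifetime Markov cohort model with half-cycle corrected
    discounted QALYs and costs, and performs incremental cost-effectiveness
    analysis with dominance and frontier identification, GDP-based threshold
    classification, age-subgroup analysis, deterministic one-way sensitivity
    analysis, and probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves.
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
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
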