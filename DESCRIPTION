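Package: fracCEA
Title: Cost-Effectiveness of Radiotherapy Fractionation Schedules via
    Markov Cohort Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov cohort state-transition modelling for the
    cost-effectiveness analysis of hypofractionated versus conventionally
    fractionated radiotherapy in early-stage glottic cancer, from the
    perspective of the Brazilian public and private health systems. Provides
    a declarative model-definition format with tunnel-state expansion for
    duration-dependent transition probabilities and costs, discounted
    cost/QALY/life-year accumulation, incremental cost-effectiveness analysis
    (ICER, dominance, net monetary benefit), one-way deterministic sensitivity
    analysis with tornado ranking, probabilistic sensitivity analysis with
    method-of-moments beta/gamma distributions and cost-effectiveness
    acceptability curves, a random-model generator, and an individual-level
    microsimulation oracle for validating the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
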