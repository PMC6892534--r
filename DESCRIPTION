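Package: trajsim
Title: Simulation-Based Evaluation of Longitudinal Exposure Trajectory
    Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates cohorts of a repeatedly measured exposure (infant
    weight at ages 0, 1 and 2 years) and a later continuous outcome
    (glycated haemoglobin at age 40) under alternative causal structures,
    and compares three common analysis strategies for longitudinal
    exposures: z-score profile plots stratified by outcome, linear mixed
    models with the outcome as a covariate, and a two-step approach that
    models growth agnostic to the outcome before relating extracted growth
    rates to the outcome by logistic regression.  Includes a purpose-built
    random-intercept and random-slope linear mixed model with first-order
    autocorrelated within-subject errors, fitted by direct optimisation of
    the marginal (restricted) likelihood, and a Monte-Carlo harness with
    empirical percentile confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr
Config/testthat/edition: 3
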