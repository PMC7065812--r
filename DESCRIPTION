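Package: leadlag
Title: Lead-Lag Decision Models for Reward Optimization During Motor Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sequential decision making during motor
    learning. Implements windowed lead-lag target-selection models with a
    Heaviside reward, dynamic-programming and brute-force solvers for
    globally optimal target sequences under a monotone (never-larger)
    constraint, grid-search fitting of lead/lag/lead-lag policies to observed
    choices with nested F-test model comparison, exponential learning-curve
    fits, moving-window bias-variance decomposition of 2-D endpoint error,
    and a reward-schedule (exploitation-horizon) analysis for visuomotor
    rotation experiments, including horizon-adjusted and cross-validated
    predictive correlations. A damped point-mass task simulator and
    synthetic-data generators make every stage testable without the original
    study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
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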