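Package: pdmboost
Title: Phenotype Distribution Models via Componentwise Gradient Boosting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the spatial distribution of a quantitative livestock trait
    (village chicken body weight) as a smooth additive function of gridded
    environmental covariates. Provides the full analysis pipeline: conversion
    of biweekly group weighings to average individual weights with the standard
    record filters, per-household least-squares means at the phase-average week
    from a common-intercept household-slope growth model, componentwise L2
    gradient boosting with penalized B-spline (P-spline) base-learners and
    resampled-risk early stopping, variable importance by accumulated in-bag
    risk reduction, spatial prediction surfaces with environmental-range
    masking, breed-by-region suitability ranking, and prediction-precision
    reports. A synthetic-data module generates georeferenced households,
    smooth covariate fields and contaminated weight records so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    emmeans,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
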