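Package: supergee
Title: Simulation and Risk-Factor Analysis for the Super G Rate-Control Motor Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless simulator of the Super G web-based rate-control motor
    task (1-D keyboard-driven dynamics sampled at 100 Hz), extraction of the
    four within-session skill metrics (scaling ratio, time of reversal, time
    in target, response time), a synthetic cohort generator with the covariate
    structure of a MindCrowd-style Alzheimer-risk sample (age, sex, APOE e4
    carrier status, education, paired-associates learning, simple visual
    reaction time), and the study's statistical battery: Wilcoxon rank-sum and
    chi-square comparisons, variance-inflation and Cook's-distance filtering,
    and five multivariable linear/logistic regression models linking task
    performance to Alzheimer disease risk factors, with parameter-recovery
    and type-I-error calibration against the generative model.
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
    MASS,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble
LinkingTo:
    Rcpp
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
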