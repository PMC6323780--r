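Package: misalignr
Title: Chronic Circadian Misalignment Analysis for Drosophila Activity Monitor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for studying the consequences of
    chronic circadian misalignment (repeated phase shifts, e.g. 28-h
    light-dark cycles) in Drosophila Activity Monitor (DAM) experiments.
    Reads and writes TriKinetics-style monitor files, models light
    schedules and zeitgeber time, calls death from beam-break records with
    ghost-reading filtering, scores sleep by the five-minute inactivity
    rule, estimates rest:activity rhythm period and power with the
    chi-squared periodogram, fits Kaplan-Meier curves, log-rank tests and
    Cox proportional-hazards models (including sleep-matched cohorts), and
    cross-classifies differential-expression results by misalignment
    versus aging regulation. A seeded synthetic-cohort generator with
    entrained activity, Gompertz mortality and post-mortem ghost counts
    makes every stage testable without laboratory data.
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
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
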