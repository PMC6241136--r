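Package: microhet
Title: Single-Cell Microcolony Growth Heterogeneity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of nongenetic growth-rate heterogeneity in clonal yeast
    microcolony populations imaged by time-lapse microscopy. Estimates
    per-colony exponential growth rates from hourly area series, excludes
    respiration-deficient (petite) colonies by MitoTracker intensity
    thresholding selected through a medcouple skewness scan, estimates
    residual petite contamination, characterises stress-reporter expression
    versus growth, quantifies Msn2 nuclear-occupancy dynamics, and links
    colonies across an acute heat shock to model single-cell survival. A
    seeded synthetic-data generator reproduces the heterogeneity structure
    the analysis assumes so every stage is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    lme4,
    mgcv,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
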