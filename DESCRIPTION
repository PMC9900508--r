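Package: trialcea
Title: Trial-Based Cost-Effectiveness Analysis for Internet-Delivered CBT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for trial-based health-economic evaluation of a
    two-arm randomised trial of internet-delivered cognitive behaviour therapy,
    with body dysmorphic disorder as the motivating indication. Provides a
    synthetic trial generator with missing-at-random dropout, TIC-P style
    resource-use costing under nested clinic, health-care and societal
    perspectives, EQ-5D utility indexing, random-intercept mixed-model
    difference-in-differences estimation, nonparametric bootstrap of
    incremental costs and effects, incremental cost-effectiveness ratios,
    net-benefit acceptability curves, cost-effectiveness plane summaries,
    and complete-case and unemployment-exclusion sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
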