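Package: kmpool
Title: Two-Track Treatment-Effect Estimation from Pooled Trial Aggregates
    and Registry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates adjuvant treatment effects on disease-free survival in
    Stage II colon cancer along two tracks and compares them. The trial track
    reconstructs pseudo individual-patient data from digitized Kaplan-Meier
    curves and numbers-at-risk tables, then fits pooled and multilevel
    (trial-frailty) Cox models. The real-world track estimates
    propensity-adjusted hazard ratios in an observational cohort by 1:1
    caliper matching, stabilized inverse-probability weighting, and
    quintile stratification. The two tracks are compared with a z-test on
    the difference of log hazard ratios. A synthetic-data module simulates
    multi-trial survival data with between-trial heterogeneity and a
    registry-style cohort with confounding by indication, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    flexsurv,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
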