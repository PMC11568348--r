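Package: spatialfda
Title: Functional Data Analysis of Spatial Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end functional data analysis of spatial single-cell imaging
    data. Estimates spatial summary functions (Ripley's K, nearest-neighbor G,
    and the variance-stabilized L) per tissue sample with edge corrections and
    theoretical or label-permutation baselines for complete spatial randomness,
    reduces the resulting curves with (multilevel) functional principal
    component analysis, and relates them to patient outcomes through penalized
    functional Cox and scalar-on-function regression models with pointwise
    confidence bands. Includes seed-deterministic simulators for Poisson and
    Thomas cluster point processes and for outcome data with a known functional
    covariate effect, so every stage of the pipeline is testable offline.
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
    utils
Suggests:
    mgcv,
    pracma,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
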