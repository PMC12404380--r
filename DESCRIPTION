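Package: prospam
Title: Spurious Prospective Associations in Two-Wave Panel Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing whether prospective (cross-lagged) regression
    effects between two constructs measured at two occasions can be explained
    without any causal effect between the constructs. Implements closed-form
    expected standardized regression effects from a six-correlation two-wave
    structure (adjusted lagged effects, difference-score effects and the
    change-on-change effect), the sign-pattern diagnostic separating true
    increasing/decreasing effects from spurious ones, the four-parameter
    trait-state generative model (SPAM) with maximum-likelihood fitting and
    standard SEM fit indices (chi-square, CFI, TLI, RMSEA), exact and
    stochastic multivariate-normal simulation, random-effects meta-analysis of
    Fisher-z transformed correlations and effects, and an end-to-end
    evaluation pipeline for pooled correlation sets and raw two-wave datasets.
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
    MASS,
    metafor,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
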