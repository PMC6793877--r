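Package: effortvalue
Title: Prospect-Theoretic Valuation of Gains and Losses in Effort-Based Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling accept/reject decisions over 50:50 mixed
    gambles in physical-effort and financial domains. Provides the lottery
    grid designs (121 gain-by-loss combinations over a viscous-resistance or
    dollar scale), a space of candidate prospect-theory choice models
    (loss aversion, value sensitivity, nonlinear effort encoding, reference
    shifts) with logistic choice likelihoods, per-subject multi-restart
    maximum-likelihood fitting, group-level random-effects Bayesian model
    selection with protected exceedance probabilities and Bayesian omnibus
    risk, Monte-Carlo model confusion analysis, a synthetic-cohort generator
    for parameter-recovery studies, and the descriptive statistics used to
    summarise choice behaviour (rejection matrices, Mann-Kendall trend
    tests, subjective-value tables and loss/gain valuation ratios).
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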