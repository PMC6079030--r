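Package: vsprl
Title: Reinforcement-Learning Analysis of Self-Protective Social Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing reciprocal social-evaluation behaviour across
    development. Generates constrained pseudorandom 75-trial task designs,
    simulates cohorts of agents whose partner-evaluation decisions follow a
    delta-rule update of the value of self-protection (VSP) with age-linked
    learning rates, builds trial-wise current/accumulated-feedback predictors,
    fits per-participant logistic influence models and a grid-search
    maximum-likelihood reinforcement-learning model, tests VSP-conditioned
    partner-derogation bias, estimates age trajectories with parametric and
    bootstrap regression, and runs bootstrap mediation with Grubbs outlier
    screening. All analyses are exercised end-to-end on synthetic cohorts.
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
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
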