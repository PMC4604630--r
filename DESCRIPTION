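Package: misens
Title: Delta-Weighting Sensitivity Analysis for Multiple Imputation
    under Missing Not at Random
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Selection-model-based sensitivity analysis for multiple
    imputation when the outcome may be missing not at random (MNAR).
    Implements proper Bayesian imputation of a single partially observed
    outcome (normal-linear and logistic), Rubin's-rules pooling, the
    importance-reweighting of per-imputation estimates by
    exp(-delta * sum of imputed values) with its weighted variance,
    per-imputation weight diagnostics, and graphical selection of a
    plausible range for the sensitivity parameter delta. Includes a
    scenario-driven Monte-Carlo framework that generates data under
    bivariate-normal and logistic outcome models with a logistic
    missingness mechanism, and quantifies missingness predictability by
    AUROC.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
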