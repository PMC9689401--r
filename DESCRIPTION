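Package: riskratio
Title: Relative Risk Estimation for Common Binary Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimators of association for binary outcomes on the risk-ratio
    scale. Provides closed-form 2x2 and stratified Mantel-Haenszel estimators
    of the relative risk, odds ratio, prevalence ratio and prevalence odds
    ratio with log-scale Wald inference; an iteratively reweighted least
    squares engine for logistic, modified (robust) Poisson and log-binomial
    regression with model-based and HC0 sandwich covariance; a synthetic
    cohort generator under a log-link true model; and a simulation harness
    quantifying how the odds ratio overstates the relative risk when the
    outcome is common, including confidence-interval coverage and
    non-collapsibility experiments. A command-line interface exposes table
    analysis, model fitting, model comparison and simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr,
    yaml
Config/testthat/edition: 3
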