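Package: panelbench
Title: Benchmarking Nonprobability Web-Panel Quota Surveys Against
    Probability Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation toolkit for assessing selection bias
    in volunteer web-panel quota surveys. Generates finite synthetic
    populations with known covariate-dependent outcomes, probability-survey
    response propensities and panel-joining propensities; simulates
    quota-controlled recruitment (basic and modified quota schemes, with
    omnibus pre-screening and quota relaxation); selects additional quota
    variables by forward stepwise logistic regression or bivariate
    association screening; poststratifies samples to external margins;
    compares surveys to aggregate or microdata benchmarks via odds ratios,
    absolute-odds-ratio summaries and bootstrap standard errors; and tests
    cross-panel consistency with a cluster-robust marginal logistic model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    sandwich,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
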