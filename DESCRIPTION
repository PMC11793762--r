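Package: serialrisk
Title: Serial Validation of Static Clinical Risk Models in Longitudinal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating static clinical prediction models applied
    consecutively (day by day) in longitudinal cohorts, motivated by serial
    risk assessment of adverse maternal outcomes in preeclampsia. Provides a
    long-format longitudinal cohort data model with validation, a calibrated
    synthetic cohort generator with a latent-severity process and known
    ground-truth outcome model, last-observation-carried-forward and
    chained-equations multiple imputation, configurable logistic risk scores
    with multi-group probability stratification, daily risk-set construction
    with carry-forward of the latest measurements, per-day precision-recall
    and ROC AUCs with bootstrap confidence intervals, group likelihood
    ratios, decision-curve (net benefit) analysis, risk-group transition
    (Sankey) accounting, and an end-to-end reproducible pipeline.
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
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
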