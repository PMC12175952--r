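Package: doseflow
Title: Bayesian Dose Finding and Remote Hemodynamic Monitoring Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools for small adaptive tolerability trials monitored by
    implanted hemodynamic sensors. Implements a one-parameter power-model
    continual reassessment method (CRM) with Gamma-prior posterior
    summaries by adaptive quadrature, sequential trial simulation and
    operating characteristics; a daily remote-monitoring pipeline for
    derived resistances (TPR, TSR, PVR), rolling 3-day averages,
    baseline-adjusted cohort curves, time-to-stability detection,
    withdrawal alerting and paired endpoint statistics; and a synthetic
    cohort generator with exponential pharmacodynamic onset/offset
    kinetics and dose-proportional exposure for end-to-end testing and
    parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    survival,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
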