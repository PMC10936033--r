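Package: twamap
Title: Time-Weighted Average MAP Hypotension Exposure and Cardiac
    Surgery-Associated Acute Kidney Injury
Version: 0.1.0
Authors@R:
    person("INSPIRE", "Pipeline Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Computes threshold-based intraoperative hypotension exposure
    metrics (area under the threshold, time-weighted average MAP below a
    cutoff, minutes below threshold) from irregularly sampled invasive mean
    arterial pressure during cardiopulmonary bypass, adjudicates cardiac
    surgery-associated acute kidney injury by the KDIGO creatinine criteria,
    assembles analysis-ready cohorts from INSPIRE-style relational CSV
    tables, and fits crude and covariate-adjusted logistic regression models
    with sensitivity and subgroup analyses. Includes a synthetic cohort
    generator with known ground truth so the whole pipeline is testable
    without access to the source registry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
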