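Package: cathex
Title: Catastrophic Household Health Expenditure Analysis for Complex Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of the incidence and intensity of catastrophic
    out-of-pocket household health expenditure from complex-survey microdata:
    weighted headcount, catastrophic overshoot and mean positive overshoot at a
    configurable budget-share threshold; adult-equivalent consumption quintiles
    and weighted fractional ranks; the concentration index with delta-method
    standard errors and cluster-bootstrap confidence intervals; regression-based
    allocation of jointly reported comorbidity treatment costs to individual
    illnesses; and quintile-stratified Poisson rate-ratio models with
    cluster-robust variance. Includes a synthetic household-survey generator
    with known ground truth, calibrated to an urban Nepalese household survey,
    so every estimator can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    sandwich,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
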