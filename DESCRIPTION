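Package: grayzone
Title: Two-Threshold ('Gray Zone') Calibration of a Visual Analogue Stress Scale
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates a 0-10 visual analogue scale (VAS) of perceived stress
    against a binary reference derived from the Perceived Stress Scale (PSS14).
    Builds the empirical ROC curve, estimates the area under the curve with a
    DeLong confidence interval, locates the optimal single cut-point under three
    criteria (Youden index, sensitivity-specificity product, closest point to
    (0,1)), and replaces the single cut-point with a two-threshold gray zone
    obtained by merging a percentile bootstrap interval of optimal cut-points
    with a Two-Graph ROC (TG-ROC) inconclusive zone. Workers are classified into
    no-follow-up, at-risk, and intervention zones. A synthetic-cohort generator
    (Gaussian copula with truncated-normal marginals) emulates the structure of
    an occupational-health screening cohort so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    readxl,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
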