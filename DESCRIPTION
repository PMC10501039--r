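Package: vocscreen
Title: Urinary Volatile Organic Compound Biomarker Screening for Late-Life
    Depression and Frailty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-biomarker analysis of urinary volatile organic
    compound (VOC) profiles measured by headspace GC-MS in elderly subjects
    with major depressive disorder and/or agoraphobia versus matched
    controls. Implements the full screening pipeline: peak-table and
    cohort-table data models, a seeded synthetic-data generator calibrated
    to published group summaries, a three-rule total-ion-current filter
    cascade with exact Mann-Whitney testing of quantifier-ion areas,
    a two-class quadratic discriminant function in explicit polynomial form
    with Box's M covariance test, combined-VOC screening indices
    (unstandardized predicted values) with rank-based ROC/AUC and Youden
    cutoffs, and correlation of indices with clinical frailty and
    depression scores including polynomial curve fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    pROC,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
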