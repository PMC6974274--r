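Package: uacrscreen
Title: Diagnostic Accuracy and Cost-Saving Analysis of Semi-Quantitative
    Urine Albumin-Creatinine Ratio Screening in Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating a semi-quantitative point-of-care urine
    albumin-creatinine ratio (uACR) test against the quantitative laboratory
    standard in diabetic patients: concordance tables and diagnostic accuracy
    (sensitivity, specificity, over- and under-detected fractions, number
    needed to screen), DerSimonian-Laird random-effects pooling of outcome
    hazard ratios, a deterministic annual-cycle Markov cohort model of two
    10-year screening strategies, cost accounting with discounting, one-way
    (tornado) sensitivity analysis, and a patient-level micro-simulator plus
    synthetic-data generators used to validate the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
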