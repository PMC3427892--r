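Package: mokkenscreen
Title: Mokken Scale Item Reduction and Validation of Brief Dementia Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonparametric item response theory (Mokken scaling) tools for
    deriving and validating brief screening scales, built around the brief
    Community Screening Instrument for Dementia (CSI-D). Computes Loevinger
    scalability coefficients from Guttman error counts, checks the monotone
    homogeneity and double monotonicity assumptions (restscore and P-matrix
    methods with Crit diagnostics), performs optimal dichotomization of
    polytomous items and hierarchical item selection, scores the brief
    cognitive, informant and combined scales with the two-stage triage rule,
    and assesses screening validity by empirical ROC analysis (AUROC with
    DeLong confidence intervals, Youden-optimal cutpoints, severity- and
    education-stratified sensitivity and specificity). A seedable synthetic
    cohort generator emulates the population-survey and pilot case-control
    designs used to develop and validate the instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
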