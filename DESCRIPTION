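Package: harmdx
Title: Harm-Weighted Diagnostic Evaluation of Paired Raters Against a
    Reference Standard
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A safety-oriented toolkit for comparing diagnostic raters (for
    example an AI assistant and clinicians) against an adjudicated reference
    diagnosis on categorical tasks such as acid-base interpretation in the
    ICU. Provides free-text category harmonization, complexity-stratified
    accuracy, multi-label component-level sensitivity and specificity with
    exact Clopper-Pearson intervals, false-reassurance quantification,
    Cohen's kappa with asymptotic confidence intervals, exact McNemar and
    exact Wilcoxon signed-rank tests, a three-tier harm-weighted
    misclassification score with weight calibration and paired bootstrap
    inference, arcsine (Cohen's h) effect sizes with post-hoc power, a
    seeded synthetic-cohort generator, and a canonical 50-case ICU fixture
    reconstructed by constraint satisfaction from published marginal counts.
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
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
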