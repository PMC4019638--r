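Package: robagree
Title: Agreement Analysis for Cochrane Risk-of-Bias Assessments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for rule-based risk-of-bias (RoB) assessment of
    randomized trials and for measuring inter-rater agreement between
    rating panels.  Implements deterministic decision rules mapping
    structured trial features to the seven items of the Cochrane RoB
    tool, trial-level and meta-analysis-level aggregation of ordinal
    low/unclear/high ratings, weighted Cohen's kappa with bootstrap and
    analytic confidence intervals, Byrt interpretation bands, and a
    seeded simulator of paired panel ratings (latent truth plus
    per-rater confusion matrices) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
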