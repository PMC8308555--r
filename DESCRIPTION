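Package: hcymr
Title: Mendelian Randomization of Homocysteine on Metabolic Syndrome Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested, reproducible Mendelian-randomization (MR) pipeline for
    estimating the causal effect of circulating homocysteine on metabolic
    syndrome from genome-wide association data. Provides a synthetic
    cohort generator with a liability-threshold metabolic-syndrome model,
    genotype quality control (missingness, monomorphism, Hardy-Weinberg),
    per-variant linear and logistic association scans, instrument selection
    with greedy LD clumping and F-statistic diagnostics, summary-statistic
    harmonization, one-sample MR (Wald ratio, two-stage least squares with a
    logistic second stage, weighted genetic risk scores) and two-sample MR
    (inverse-variance weighted, weighted median, MR-Egger) with Cochran Q,
    Egger-intercept and I2GX sensitivity statistics. Ships a packaged
    five-variant homocysteine instrument set from Korean population cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
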