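Package: stonemr
Title: Two-Sample Mendelian Randomization Pipeline for Adiposity and
    Kidney Stone Disease
Version: 0.1.0
Authors@R:
    person("stonemr", "developers", email = "stonemr@example.org",
           role = c("aut", "cre"))
Description: Summary-statistics causal-inference toolkit linking adiposity
    to kidney stone disease: fixed-effects GWAS meta-analysis with Cochran
    Q / I-squared heterogeneity filtering, instrument selection with greedy
    LD clumping and strength diagnostics (R-squared, F), allele
    harmonization including frequency-based palindrome resolution,
    univariable Mendelian randomization estimators (Wald ratio,
    inverse-variance weighted, MR-Egger, weighted median, contamination
    mixture) with heterogeneity, leave-one-out and Steiger directionality
    sensitivity analyses, multivariable MR, and mediation decomposition
    with delta-method uncertainty. Includes a synthetic summary-statistics
    generator with known causal structure so the full pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
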