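Package: stratmr
Title: Biologically Stratified Two-Sample Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample Mendelian randomization from GWAS summary statistics
    with instrument stratification by the sign of each variant's effect on a
    downstream biological indicator trait. Provides summary-statistics
    harmonization (allele alignment, orientation to the exposure-increasing
    allele, linkage-disequilibrium proxy substitution), Steiger directionality
    filtering, inverse-variance weighted, MR-Egger, weighted-median and
    penalized-weighted-median causal estimators with Cochran's Q, I-squared
    and Egger-intercept diagnostics, and a seeded simulator of linked
    exposure/indicator/outcome summary-statistics tables with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
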