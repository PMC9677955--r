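Package: ldscmr
Title: LD Score Regression and Two-Sample Mendelian Randomization for
    GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking polygenic traits from genome-wide
    association study (GWAS) summary statistics. Implements LD score
    regression for heritability, confounding-intercept and cross-trait
    genetic-correlation estimation with block-jackknife standard errors;
    a staged instrumental-variable selection protocol (p-value threshold,
    LD clumping, outcome-association and confounder exclusion,
    palindromic-variant handling, proxy substitution); five two-sample
    Mendelian randomization estimators (random-effects inverse-variance
    weighted, Egger regression, weighted median, simple and weighted
    mode); and heterogeneity / horizontal-pleiotropy diagnostics
    including Cochran's and Rucker's Q, the Egger intercept test and a
    simulation-based residual outlier test. A synthetic summary-statistics
    generator with known heritability, genetic correlation and planted
    pleiotropy provides ground truth for every stage, so the full
    screening pipeline is testable without cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
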