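Package: mrflow
Title: Two-Sample Mendelian Randomization Workflows from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) toolkit built on
    GWAS summary statistics: instrument selection (p-value thresholding, greedy
    LD clumping, F-statistic filtering), allele harmonization with palindromic
    resolution, the standard estimator suite (inverse-variance weighted with a
    Cochran's Q fixed/random gate, MR-Egger, weighted median, maximum
    likelihood), sensitivity diagnostics (heterogeneity, Egger-intercept
    pleiotropy, leave-one-out, funnel and scatter data), multivariable MR,
    DerSimonian-Laird meta-analysis across cohorts, and two-step mediation MR
    with delta-method confidence intervals for the mediated proportion. A
    seeded synthetic summary-statistics generator with known causal truth makes
    every stage testable without consortium downloads.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
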