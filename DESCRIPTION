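Package: tsremeta
Title: Two-Stage Random-Effects Meta-Analysis for Unbalanced Panels of
    Effect Sizes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a two-stage random-effects (2SRE) estimator for
    meta-analysis and meta-regression of unbalanced panels of effect-size
    estimates, where each independent group (study or data sample) may
    contribute one or several observations.  The estimator separates
    sampling error (with known standard errors) from non-sampling
    heterogeneity at both the group and observation level, allows a
    user-specified within-group correlation of sampling errors, and
    derives variance-minimizing weights by the method of moments.  The
    package also provides comparator estimators (simple and group means,
    fixed-effect inverse-variance, DerSimonian-Laird, correlated- and
    hierarchical-effects working models, multilevel REML), trim-and-fill
    and PET-PEESE publication-bias corrections, cluster bootstrap and
    cluster-robust standard errors, leave-one-out cross-validated fit
    statistics, jackknife model averaging, and a Monte Carlo harness for
    estimator comparison on synthetic meta-datasets.  Developed for
    syntheses of value-per-statistical-life (VSL) estimates but
    applicable to any effect size reported with a standard error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
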