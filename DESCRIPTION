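Package: fisherset
Title: Self-Contained Gene-Set Analysis with a Truncated Fisher Statistic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Self-contained differential-expression analysis of gene sets from
    two-group expression data. Combines per-gene p-values (pooled t or Wilcoxon
    rank-sum) with a Fisher statistic whose individual p-values are truncated
    at a floor p_min, so that no small subset of genes can by itself render a
    set significant. Provides the analytic chi-squared null and Monte-Carlo /
    mixture nulls for the truncated statistic, threshold solvers for the
    number of dominant genes required for set significance, five comparison
    statistics (Stouffer, Tail Strength, Kolmogorov-Smirnov, SAM-GS, Hotelling
    T2), phenotype-label permutation p-values with log-log regression
    extrapolation for p-values below the permutation resolution, permutation
    derived gene-pair dependency factors, Benjamini-Hochberg FDR across set
    collections, GMT input, and a synthetic-data engine for power, type-I,
    method-correlation and extrapolation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
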