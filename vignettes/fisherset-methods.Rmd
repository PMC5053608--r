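---
title: "Methods: self-contained gene-set analysis with a truncated Fisher statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-contained gene-set analysis with a truncated Fisher statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fisherset)
```

## The model

`fisherset` tests *self-contained* differential expression of gene sets: a
set is scored only from its own genes, never against the rest of the
transcriptome. Given two phenotype groups with `n1` and `n2` samples, each
gene `k` of a set of size `K` receives a two-sample p-value `p_k` (pooled t
by default, Wilcoxon rank-sum as an alternative), and the set is scored by
the Fisher combination statistic with a truncation floor:

    F = -2 * sum_k log(max(p_k, p_min))

With `p_min = 0` this is the classical Fisher statistic, chi-squared with
`2K` degrees of freedom when the genes are independent. The floor `p_min`
caps any single gene's contribution at `-2*log(p_min)`: a set can then only
become significant when *several* genes are individually significant, which
protects against one extreme transcript carrying an entire pathway. The
price is that the chi-squared null no longer applies, so the package
provides the truncated null in two forms (below), plus five comparison
statistics (Stouffer, Tail Strength, a one-sided Kolmogorov–Smirnov
departure, SAM-GS, Hotelling T²) behind the same permutation machinery.

## Null distributions for the truncated statistic

`build_modified_null()` represents the null of `F` under `p_min > 0`:

* **Monte-Carlo** (default): `n_draws` sets of `K` uniforms pushed through
  the statistic, stored sorted. The threshold tables are stable from about
  `1e6` draws; that is the default and the size the package's own checks
  use.
* **Analytic mixture** (used in tests as the independent oracle): the
  number of floored genes is Binomial(`K`, `p_min`) contributing exactly
  `-2*log(p_min)` each; each unfloored gene contributes a truncated
  exponential density on `[0, -2*log(p_min)]`, convolved by FFT. The grid
  step is `-2*log(p_min)/grid_points`; upper tails are evaluated half a
  step below the query so the all-floored atom at the maximum support stays
  in the tail.

Two solvers sit on top. `dominant_gene_threshold(K, j)` answers "how small
must `j` dominant genes' p-values be for the whole set to reach level
alpha under the *untruncated* statistic when the remaining genes sit at
`p_rest = .5`?" — with `K = 10` a single gene at `3.6e-6` suffices at
alpha `.01`, which is the pathology the truncation removes.
`minimum_genes_required(K, p_min)` answers the converse under the
truncated statistic: the smallest number of genes at the floor that carries
the set past the `(1 - alpha)` null quantile, with ties broken upward
(strict `>`). At `K = 10`, `p_min = .05`, five genes are required.

## Permutation inference

`permute_set()` recomputes the per-gene tests and the set statistic under
`B` random relabellings of the samples (group sizes preserved, sampled with
replacement from the arrangement space; exhaustive enumeration is available
when there are at most `1e5` arrangements). The p-value convention is
`(count_ge + 1) / (B + 1)`, counting ties as extreme: it can never reach
zero, respects the `1/(B+1)` resolution bound, and keeps the test valid for
any dependence among genes. The observed labelling occupies column one; the
per-gene tests for all `B+1` labellings are computed by closed-form matrix
algebra (group sums and sums of squares via two matrix products), which is
what makes the replicated studies below affordable.

## Extrapolating below the permutation resolution

Strongly differentiated datasets push set p-values far below any feasible
`1/B`. The package models the relationship between the independence-null
p-value `p_uncorr` (chi-squared, or truncated null) and the permutation
p-value `p_corr` by a power law, `p_corr = b * p_uncorr^m`, fitted by
ordinary least squares on the log-log scale. `fit_extrapolation()` builds
the pairs from a single permutation run — each permuted statistic gets an
independence p and a rank-based p among the `B` permuted statistics — over
the window `p_corr` in `[10/B, .5]` by default: below `10/B` rank
granularity distorts the log, above `.5` the tail model is irrelevant.
`run_regression_study()` instead pools one pair per replicate dataset (the
observed statistic's two p-values), the design used to calibrate against
correlated synthetic data. `extrapolate_pvalue()` then applies
`min(1, b * p_uncorr^m)`.

One sidedness choice matters here and is deliberate. All reported gene
tests are two-sided. But inside the regression study the per-gene p-values
default to one-sided (`alternative = "greater"`): a two-sided p-value is an
even function of the t statistic, so a pairwise gene correlation `r`
survives into the combined statistic only at order `r²`, and the fitted
slope stays near 1 even for clearly correlated data; a monotone (one-sided)
transform preserves the correlation at first order, and at `r = .05`,
`K = 100`, `200` patients the study recovers a slope near `.27` — a
roughly 12-fold correction already at `p_uncorr = 1e-2`. The slope is the
meaningful output; the multiplier `b` is less stable across permutation
budgets.

## Gene-pair dependencies

During the same permutation run the package records, at level `lambda`
(default `.05`), which genes are "significant" in each relabelling.
`dependency_factors()` turns the marginal and joint counts into the factor
`P(A and B) / (P(A) P(B))` — algebraically `P(A|B)/P(A)` — which is
exactly symmetric by construction, near 1 for independent genes, and equal
to `1/P(A)` for a perfectly duplicated gene. These probabilities describe
the permutation ensemble, not the observed labelling; they expose which
genes co-fire, not which are differentially expressed.

## The synthetic-data engine

`sim_config()` fixes the generative setting of all study drivers: `K`
genes, `n1 + n2` samples, normal expression with standard deviation
`sigma = 1`, a group-2 mean shift `mu2 - mu1` (the power studies use
`.15`), and optional inter-gene correlation imposed by Cholesky-factoring a
compound-symmetric matrix (or the "mixed" rule
`0.15 + 0.15*sin(2*pi*k1*k2)`, symmetrised and eigen-repaired with a
`1e-6` floor before factoring). The drivers and their default scales:

* `run_power_study()` / `run_type1_study()`: fraction of replicates with
  permutation p below `.05`. The package's reference checks use 2,000
  replicates at `B = 500` — at those sizes the binomial standard error on a
  power of `.84` is about `.008`, small against the `±.03` agreement band
  used — with 100, 200 and 50 patients per group for power, and 50 per
  group for type-I error.
* `run_correlation_study()`: replicate null sets, every method's
  permutation p computed from the *same* 200 permutations per replicate
  (sharing removes budget noise from the comparison), 2,000 replicates.
* `run_regression_study()`: 400 replicate correlated datasets at
  `B = 5000` (the slope estimate's seed-to-seed spread at 200 replicates
  is a sizeable fraction of the agreement band; 400 halves its variance).

What the generator emulates is the statistical skeleton of two-group
microarray comparisons: per-gene normality on a common scale, equal
variances, homogeneous shifts, exchangeable samples. What it does not
emulate: heavy-tailed and heteroskedastic expression, probe-level
artefacts, normalisation effects, realistic (block- or pathway-structured)
correlation, and confounded designs. Passing the simulation checks
therefore validates the statistical machinery, not robustness to those
data pathologies; on real data the Wilcoxon option and the permutation
null carry most of that burden.

## Numerical choices and degenerate inputs

* p-values are clamped to `1e-300` before any logarithm.
* Degenerate genes (identical values in both groups) get `p = 1` with a
  warning; all-tied Wilcoxon genes likewise.
* Wilcoxon uses exact enumeration up to 20 total samples without ties,
  otherwise the normal approximation with tie and continuity correction.
  Inside the permutation engine the approximation is used throughout so
  that observed and permuted statistics share one definition.
* Stouffer maps small p to large z (`qnorm(1 - p)`) and reads the
  consolidated p from the upper tail; p-values at 0 or 1 are clamped to
  machine-safe bounds with a warning.
* The Kolmogorov–Smirnov statistic is the one-sided `D+ = max(k/K -
  p_(k))`: only an excess of small p-values counts as evidence. (The
  two-sided distance also fires on sets whose p-values cluster near 1 and
  is essentially uncorrelated with the other five statistics on null
  data.)
* Hotelling T² uses the Moore–Penrose pseudo-inverse when the pooled
  covariance is singular (`K >= n1 + n2 - 2`) and records the effective
  rank.
* Benjamini–Hochberg uses the strict inequality `p_(k) < k*alpha/K`; ties
  in p are ordered by set name so retained prefixes are reproducible. The
  strict form differs from the usual `<=` only when a p-value exactly
  equals its threshold.
* Gene matching between GMT sets and the matrix is exact and
  case-sensitive; sets reduced below two genes are skipped with a warning,
  and `genes_found` preserves the evidence of dropping.
* Every driver consumes one master seed; reruns are byte-identical.

## A worked example

```{r example, eval = FALSE}
expr <- system.file("extdata", "synthetic_expression.tsv", package = "fisherset")
labs <- system.file("extdata", "synthetic_labels.tsv", package = "fisherset")
gmt  <- system.file("extdata", "synthetic_sets.gmt", package = "fisherset")
mat <- read_expression(expr, labs)
res <- run_analysis(mat, gmt, B = 1000, p_min = .05,
                    gene_test = "wilcoxon", seed = 1)
res[, c("set", "genes_found", "statistic", "p_perm", "bh_retained")]
```

The bundled fixtures are synthetic (generated, labelled as such): ten
genes carry a simulated disease shift, and the analysis retains exactly
the set collecting them.

## Known limitations

* The truncated-null Monte-Carlo representation is memory-proportional to
  `n_draws`; the analytic mixture is preferable for repeated tail queries
  at large `K`.
* The extrapolation law is a straight line in log-log space; on real data
  with mixed correlation structure curvature is visible and the
  extrapolated tail p-values should be read as order-of-magnitude
  statements.
* Competitive enrichment (GSEA-style), SVD/metagene scores, global
  logistic-regression tests and ANCOVA are intentionally out of scope, as
  are platform preprocessing, probe collapsing and normalisation.
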