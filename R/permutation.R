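# samples x (B+1) group-1 indicator matrix; column 1 is the observed
# labelling. Permutations are uniform draws from the label arrangements
# preserving group sizes; when `exhaustive`, all C(n, n1) arrangements are
# enumerated instead (only offered while that count is <= 1e5).
permutation_indicators <- function(g1, B, seed = NULL, exhaustive = FALSE) {
  n <- length(g1)
  n1 <- sum(g1)
  if (exhaustive) {
    if (choose(n, n1) > 1e5) stop("too many arrangements for exhaustive mode")
    combs <- utils::combn(n, n1)
    Gmat <- matrix(0, n, ncol(combs) + 1L)
    Gmat[, 1L][g1] <- 1
    for (b in seq_len(ncol(combs))) Gmat[combs[, b], b + 1L] <- 1
    return(Gmat)
  }
  if (!is.null(seed)) set.seed(seed)
  Gmat <- matrix(0, n, B + 1L)
  Gmat[, 1L][g1] <- 1
  for (b in seq_len(B)) Gmat[sample.int(n, n1), b + 1L] <- 1
  Gmat
}

# per-permutation gene p-value matrix for the configured per-gene test
perm_gene_pvalues <- function(X, Gmat, gene_test = "t",
                              alternative = "two.sided", var_equal = TRUE) {
  switch(gene_test,
         t = t_pvalue_matrix(X, Gmat, alternative, var_equal),
         wilcoxon = wilcoxon_pvalue_matrix(X, Gmat),
         stop("unknown gene test: ", gene_test))
}

perm_set_stats <- function(X, P, Gmat, method, p_min = 0, s0 = 0) {
  switch(method,
         fisher = fisher_stat_cols(P, p_min),
         stouffer = stouffer_stat_cols(P),
         tail_strength = ts_stat_cols(P),
         ks = ks_stat_cols(P),
         samgs = samgs_stat_cols(X, Gmat, s0),
         hotelling = hotelling_stat_cols(X, Gmat),
         stop("unknown set statistic: ", method))
}

#' Phenotype-permutation p-value for a gene set
#'
#' Recomputes the chosen set statistic under `B` random relabellings of the
#' samples (group sizes preserved): per permutation the per-gene test is
#' rerun and the set statistic rebuilt, and the permutation p-value is
#' `(count_ge + 1) / (B + 1)` where `count_ge` counts permuted statistics at
#' or above the observed one (ties included). This rank-based p-value is
#' valid under arbitrary inter-gene correlation and cannot fall below
#' `1/(B+1)`.
#'
#' Per-permutation per-gene significance flags at level `lambda` are
#' accumulated into marginal and pairwise counts for
#' [dependency_factors()]; the flags use t-test p-values also when the set
#' statistic itself is expression-based.
#'
#' @param mat An [expression_matrix()].
#' @param set A [gene_set()], or `NULL` to use every gene in `mat`.
#' @param method One of `"fisher"`, `"stouffer"`, `"tail_strength"`,
#'   `"ks"`, `"samgs"`, `"hotelling"`.
#' @param B Number of permutations (>= 1).
#' @param seed Integer seed for the permutation draws.
#' @param p_min Truncation floor for `method = "fisher"`.
#' @param lambda Per-gene significance level for the dependency flags.
#' @param gene_test `"t"` or `"wilcoxon"` per-gene test.
#' @param alternative Sidedness of the per-gene test.
#' @param s0 SAM-GS fudge constant.
#' @param exhaustive Enumerate all label arrangements instead of sampling.
#' @return An object of class `permutation_outcome`: observed statistic,
#'   permuted statistics, `count_ge`, `p_perm`, dependency counts.
#' @export
permute_set <- function(mat, set = NULL, method = "fisher", B = 1000,
                        seed = 1, p_min = 0, lambda = 0.05,
                        gene_test = "t", alternative = "two.sided",
                        s0 = 0, exhaustive = FALSE) {
  if (!exhaustive && B < 1) stop("B must be >= 1")
  X <- if (is.null(set)) {
    x <- mat$values
    attr(x, "genes_found") <- nrow(x)
    attr(x, "K_set") <- nrow(x)
    x
  } else set_submatrix(mat, set)
  g1 <- group1_mask(mat)
  Gmat <- permutation_indicators(g1, B, seed, exhaustive)
  B <- ncol(Gmat) - 1L
  P <- perm_gene_pvalues(X, Gmat, gene_test, alternative)
  stats_all <- perm_set_stats(X, P, Gmat, method, p_min, s0)
  obs <- stats_all[1L]
  perm <- stats_all[-1L]
  count_ge <- sum(perm >= obs)
  sig <- P[, -1L, drop = FALSE] <= lambda
  storage.mode(sig) <- "double"
  structure(list(
    method = method, p_min = if (method == "fisher") p_min else NA_real_,
    K = attr(X, "K_set"), genes_found = attr(X, "genes_found"),
    gene_ids = rownames(X),
    observed = obs, perm_stats = perm, B = B,
    count_ge = count_ge, p_perm = (count_ge + 1) / (B + 1),
    seed = seed, lambda = lambda, gene_test = gene_test,
    alternative = alternative,
    sig_counts = rowSums(sig), joint_counts = tcrossprod(sig),
    n1 = sum(g1), n2 = sum(!g1)),
    class = "permutation_outcome")
}

#' @export
print.permutation_outcome <- function(x, ...) {
  cat(sprintf(
    "permutation_outcome [%s]: observed = %.4g, B = %d, count_ge = %d, p_perm = %.4g\n",
    x$method, x$observed, x$B, x$count_ge, x$p_perm))
  invisible(x)
}

#' Fit the power-law map from independence p-values to permutation p-values
#'
#' Each permuted Fisher statistic is given two p-values: its upper tail
#' under the independence null (`p_uncorr`, chi-squared or truncated-Fisher
#' null) and its rank among all `B` permuted statistics (`p_corr`). An
#' ordinary least-squares line through `log(p_corr) ~ log(p_uncorr)` over
#' pairs with `p_corr` inside `fit_range` yields the model
#' `p_corr = b * p_uncorr^m`, which [extrapolate_pvalue()] can then apply to
#' p-values far below the permutation resolution `1/B`.
#'
#' @param outcome A `permutation_outcome` with `method = "fisher"`.
#' @param null Optional `modified_fisher_null` for `p_min > 0`; with
#'   `p_min = 0` the chi-squared null is used.
#' @param fit_range Keep pairs with `p_corr` in this interval. The default
#'   `c(10/B, .5)` discards the granular extreme ranks and the irrelevant
#'   upper half.
#' @return An object of class `regression_fit` with slope `m`, multiplier
#'   `b`, `n_points` and `fit_range`.
#' @export
fit_extrapolation <- function(outcome, null = NULL, fit_range = NULL) {
  stopifnot(inherits(outcome, "permutation_outcome"))
  if (outcome$method != "fisher")
    stop("extrapolation is defined for the Fisher statistic")
  B <- outcome$B
  if (is.null(fit_range)) fit_range <- c(10 / B, 0.5)
  Fb <- outcome$perm_stats
  K <- outcome$genes_found
  pm <- outcome$p_min
  p_uncorr <- if (!is.na(pm) && pm > 0) {
    if (is.null(null)) stop("p_min > 0 requires a modified null")
    if (null$K != K || !isTRUE(all.equal(null$p_min, pm)))
      stop("null does not match the outcome's (K, p_min)")
    null_upper_tail(null, Fb)
  } else {
    chisq_tail(Fb, K)
  }
  # rank-based p of each permuted statistic among all B of them
  p_corr <- (B - rank(Fb, ties.method = "min") + 1) / B
  keep <- p_corr >= fit_range[1] & p_corr <= fit_range[2]
  if (sum(keep) < 50)
    stop("fewer than 50 usable pairs in fit_range; increase B")
  fit <- stats::lm(log(p_corr[keep]) ~ log(p_uncorr[keep]))
  regression_fit(unname(stats::coef(fit)[2]), exp(unname(stats::coef(fit)[1])),
                 sum(keep), fit_range)
}

regression_fit <- function(m, b, n_points, fit_range) {
  if (b <= 0) stop("multiplier b must be positive")
  structure(list(m = m, b = b, n_points = as.integer(n_points),
                 fit_range = fit_range),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("regression_fit: p_corr = %.4g * p_uncorr^%.4g (%d points)\n",
              x$b, x$m, x$n_points))
  invisible(x)
}

#' Extrapolate a permutation p-value through the fitted power law
#'
#' Applies `p_corr = min(1, b * p_uncorr^m)`. Because `m < 1` for
#' positively correlated genes, the correction grows as `p_uncorr`
#' shrinks; this extends permutation inference below the `1/B` resolution.
#'
#' @param fit A `regression_fit`.
#' @param p_uncorr Independence-null p-value(s) in (0, 1).
#' @return Extrapolated p-value(s).
#' @export
#' @examples
#' fit <- regression_fit(m = .27, b = .40, n_points = 0L, fit_range = c(0, 1))
#' extrapolate_pvalue(fit, 1e-2)   # ~.115, a 12-fold correction
extrapolate_pvalue <- function(fit, p_uncorr) {
  stopifnot(inherits(fit, "regression_fit"))
  if (any(p_uncorr <= 0 | p_uncorr >= 1)) stop("p_uncorr must be in (0, 1)")
  pmin(1, fit$b * p_uncorr^fit$m)
}

#' Gene-pair dependency factors from a permutation run
#'
#' From the per-permutation significance flags recorded by
#' [permute_set()], estimates for each gene the probability `P(A)` of being
#' significant at level `lambda` in a random relabelling, and for each pair
#' the joint probability `P(A and B)`. The dependency factor
#' `P(A and B) / (P(A) * P(B))`, algebraically `P(A|B)/P(A) = P(B|A)/P(B)`,
#' is exactly symmetric and exceeds 1 for positively dependent gene pairs.
#' Pairs involving a gene never significant are undefined (`NA`).
#'
#' @param outcome A `permutation_outcome`.
#' @return An object of class `dependency_matrix` with `lambda`,
#'   `P_single`, `joint`, `factor`.
#' @export
dependency_factors <- function(outcome) {
  stopifnot(inherits(outcome, "permutation_outcome"))
  B <- outcome$B
  P_single <- outcome$sig_counts / B
  joint <- outcome$joint_counts / B
  denom <- outer(P_single, P_single)
  fac <- ifelse(denom > 0, joint / denom, NA_real_)
  ids <- outcome$gene_ids
  names(P_single) <- ids
  dimnames(joint) <- dimnames(fac) <- list(ids, ids)
  structure(list(lambda = outcome$lambda, B = B, P_single = P_single,
                 joint = joint, factor = fac),
            class = "dependency_matrix")
}

#' @export
print.dependency_matrix <- function(x, ...) {
  cat(sprintf("dependency_matrix: %d genes, lambda = %g, B = %d\n",
              length(x$P_single), x$lambda, x$B))
  invisible(x)
}

#' Write a dependency factor matrix as TSV
#'
#' Square tab-separated table with gene ids as header and row names,
#' suitable for heat-map rendering.
#'
#' @param dep A `dependency_matrix`.
#' @param path Output file path.
#' @export
write_dependency_tsv <- function(dep, path) {
  stopifnot(inherits(dep, "dependency_matrix"))
  df <- data.frame(gene = rownames(dep$factor), dep$factor,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
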