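#' Gene set
#'
#' A named set of gene identifiers, as one line of a GMT file.
#'
#' @param name Set name.
#' @param gene_ids Character vector of gene identifiers; must be non-empty.
#'   Duplicates are removed with a warning.
#' @param description Free-text description (GMT field 2).
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, gene_ids, description = "") {
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) == 0L) stop("gene set '", name, "' is empty")
  if (anyDuplicated(gene_ids)) {
    warning("duplicate gene ids in set '", name, "'; deduplicated")
    gene_ids <- unique(gene_ids)
  }
  structure(list(name = as.character(name), description = as.character(description),
                 gene_ids = gene_ids),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes\n", x$name, length(x$gene_ids)))
  invisible(x)
}

new_set_statistic <- function(method, value, K, p_min = NA_real_,
                              genes_found = K, extra = list()) {
  structure(c(list(method = method, value = as.numeric(value), K = as.integer(K),
                   p_min = p_min, genes_found = as.integer(genes_found)),
              extra),
            class = "set_statistic")
}

#' @export
print.set_statistic <- function(x, ...) {
  cat(sprintf("set_statistic [%s]: value = %.6g, K = %d%s\n",
              x$method, x$value, x$K,
              if (!is.na(x$p_min)) sprintf(", p_min = %g", x$p_min) else ""))
  invisible(x)
}

pvec <- function(p) {
  if (inherits(p, "gene_pvalues")) p$p else as.numeric(p)
}

#' Truncated ("modified") Fisher combination statistic
#'
#' Combines per-gene p-values as `F = -2 * sum(log(max(p_k, p_min)))`. The
#' truncation floor `p_min` prevents a handful of extremely small p-values
#' from dominating the set: a gene can contribute at most `-2*log(p_min)` to
#' the statistic. With `p_min = 0` this is the classical Fisher combined
#' statistic, chi-squared with `2K` degrees of freedom under independence
#' (see [chisq_set_pvalue()]); for `p_min > 0` see [build_modified_null()].
#'
#' @param p Per-gene p-values: a numeric vector or a `gene_pvalues` object.
#' @param p_min Truncation floor in `[0, 1)`.
#' @return A `set_statistic` with `method = "fisher"`.
#' @export
#' @examples
#' fisher_F(rep(0.5, 10))                  # -2 * 10 * log(.5) = 13.86
#' fisher_F(c(1e-6, rep(.5, 9)), p_min = .01)
fisher_F <- function(p, p_min = 0) {
  p <- pvec(p)
  if (length(p) == 0L) stop("empty gene set after matching")
  if (p_min < 0 || p_min >= 1) stop("p_min must be in [0, 1)")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  val <- -2 * sum(log(pmax(p, max(p_min, P_FLOOR))))
  new_set_statistic("fisher", val, length(p), p_min = p_min)
}

#' Stouffer combined z statistic
#'
#' Converts each p-value to `Z_k = qnorm(1 - p_k)` and averages:
#' `Z_s = sum(Z_k) / sqrt(K)`, standard normal under the null. Small
#' p-values map to large z, and the consolidated p-value is the upper tail
#' `1 - pnorm(Z_s)`.
#'
#' @inheritParams fisher_F
#' @return A `set_statistic` with `method = "stouffer"` and an extra element
#'   `consolidated_p`.
#' @export
stouffer_Z <- function(p) {
  p <- pvec(p)
  if (length(p) == 0L) stop("empty gene set after matching")
  if (any(p <= 0 | p >= 1)) {
    warning("p-values at 0 or 1 clamped for the normal quantile")
    p <- pmin(pmax(p, 1e-16), 1 - 1e-16)
  }
  z <- stats::qnorm(p, lower.tail = FALSE)
  zs <- sum(z) / sqrt(length(p))
  new_set_statistic("stouffer", zs, length(p),
                    extra = list(consolidated_p = stats::pnorm(zs, lower.tail = FALSE)))
}

#' Tail Strength statistic
#'
#' With p-values sorted ascending, `TS = (1/K) * sum(1 - p_(k)*(K+1)/k)`.
#' Zero in expectation under a uniform null; positive when small p-values
#' are enriched.
#'
#' @inheritParams fisher_F
#' @return A `set_statistic` with `method = "tail_strength"`.
#' @export
tail_strength <- function(p) {
  p <- pvec(p)
  if (length(p) == 0L) stop("empty gene set after matching")
  K <- length(p)
  s <- sort(p)
  val <- mean(1 - s * (K + 1) / seq_len(K))
  new_set_statistic("tail_strength", val, K)
}

#' Kolmogorov-Smirnov departure of p-values from uniformity
#'
#' One-sided D+ distance of the sorted p-values from the uniform
#' distribution: `d = max_k (k/K - p_(k))`, large when small p-values are
#' enriched. (The one-sided form is the directional one: an excess of
#' p-values near 1 does not count as evidence of differential expression.)
#'
#' @inheritParams fisher_F
#' @return A `set_statistic` with `method = "ks"`.
#' @export
ks_statistic <- function(p) {
  p <- pvec(p)
  if (length(p) == 0L) stop("empty gene set after matching")
  K <- length(p)
  s <- sort(p)
  val <- max(seq_len(K) / K - s)
  new_set_statistic("ks", val, K)
}

# submatrix of set genes present in the data; attributes record matching
set_submatrix <- function(mat, set) {
  found <- intersect(set$gene_ids, mat$gene_ids)
  if (length(found) == 0L) stop("empty gene set after matching")
  X <- mat$values[found, , drop = FALSE]
  attr(X, "genes_found") <- length(found)
  attr(X, "K_set") <- length(set$gene_ids)
  X
}

#' SAM-GS squared t-like statistic
#'
#' For each gene in the set, `d_i = (mean1_i - mean2_i) / (se_i + s0)` with
#' `se_i` the pooled standard error of the mean difference and `s0` a
#' variance-stabilising fudge constant; the set statistic is `sum(d_i^2)`.
#' With `s0 = 0` and a single gene this is the squared pooled t statistic.
#'
#' @param mat An [expression_matrix()].
#' @param set A [gene_set()]; genes absent from `mat` are dropped and
#'   reflected in `genes_found`.
#' @param s0 Non-negative fudge constant added to each standard error.
#' @return A `set_statistic` with `method = "samgs"`.
#' @export
samgs_statistic <- function(mat, set, s0 = 0) {
  if (s0 < 0) stop("s0 must be non-negative")
  X <- set_submatrix(mat, set)
  g1 <- group1_mask(mat)
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- rowMeans(X[, g1, drop = FALSE])
  m2 <- rowMeans(X[, !g1, drop = FALSE])
  ss1 <- rowSums((X[, g1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((X[, !g1, drop = FALSE] - m2)^2)
  se <- sqrt((ss1 + ss2) / (n1 + n2 - 2) * (1 / n1 + 1 / n2))
  dd <- m1 - m2
  denom <- se + s0
  if (any(denom == 0)) {
    if (any(denom == 0 & abs(dd) > 0))
      stop("zero standard error with nonzero mean difference and s0 = 0")
    d <- ifelse(denom == 0, 0, dd / denom)
  } else d <- dd / denom
  new_set_statistic("samgs", sum(d^2), attr(X, "K_set"),
                    genes_found = attr(X, "genes_found"))
}

#' Hotelling T-squared two-sample statistic for a gene set
#'
#' `T2 = n1*n2/(n1+n2) * t(d) %*% solve(S, d)` where `d` is the vector of
#' group mean differences over the set genes and `S` the pooled covariance
#' matrix. When `S` is singular (set size at or above `n1 + n2 - 2`) the
#' Moore-Penrose pseudo-inverse is used and the effective rank is recorded
#' in the result.
#'
#' @inheritParams samgs_statistic
#' @return A `set_statistic` with `method = "hotelling"` and an extra
#'   element `rank` (effective rank of the pooled covariance used).
#' @export
hotelling_T2 <- function(mat, set) {
  X <- set_submatrix(mat, set)
  g1 <- group1_mask(mat)
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples for a covariance")
  val <- hotelling_value(X, g1, n1, n2)
  new_set_statistic("hotelling", val$t2, attr(X, "K_set"),
                    genes_found = attr(X, "genes_found"),
                    extra = list(rank = val$rank))
}

hotelling_value <- function(X, g1, n1, n2) {
  X1 <- X[, g1, drop = FALSE]
  X2 <- X[, !g1, drop = FALSE]
  d <- rowMeans(X1) - rowMeans(X2)
  S <- ((n1 - 1) * stats::cov(t(X1)) + (n2 - 1) * stats::cov(t(X2))) / (n1 + n2 - 2)
  K <- nrow(X)
  rk <- qr(S)$rank
  t2 <- if (rk < K) {
    drop(t(d) %*% MASS::ginv(S) %*% d)
  } else {
    drop(crossprod(d, solve(S, d)))
  }
  list(t2 = n1 * n2 / (n1 + n2) * t2, rank = rk)
}

# ---- vectorised set statistics over a permutation p-value matrix ----------
# P is genes x (B+1); returns a numeric vector, one statistic per column.

fisher_stat_cols <- function(P, p_min = 0) {
  -2 * colSums(log(pmax(P, max(p_min, P_FLOOR))))
}

stouffer_stat_cols <- function(P) {
  P <- pmin(pmax(P, 1e-16), 1 - 1e-16)
  colSums(stats::qnorm(P, lower.tail = FALSE)) / sqrt(nrow(P))
}

ts_stat_cols <- function(P) {
  K <- nrow(P)
  S <- apply(P, 2L, sort)
  colMeans(1 - S * (K + 1) / seq_len(K))
}

ks_stat_cols <- function(P) {
  K <- nrow(P)
  S <- apply(P, 2L, sort)
  apply(seq_len(K) / K - S, 2L, max)
}

# SAM-GS over all columns of a group-1 indicator matrix
samgs_stat_cols <- function(X, Gmat, s0 = 0) {
  n <- ncol(X)
  n1 <- colSums(Gmat)
  n2 <- n - n1
  S1 <- X %*% Gmat
  Q1 <- (X * X) %*% Gmat
  S <- rowSums(X); Q <- rowSums(X * X)
  m1 <- sweep(S1, 2, n1, "/")
  m2 <- sweep(S - S1, 2, n2, "/")
  ss1 <- Q1 - sweep(S1^2, 2, n1, "/")
  ss2 <- (Q - Q1) - sweep((S - S1)^2, 2, n2, "/")
  sp2 <- sweep(ss1 + ss2, 2, n1 + n2 - 2, "/")
  se <- sqrt(sweep(sp2, 2, 1 / n1 + 1 / n2, "*"))
  colSums(((m1 - m2) / (se + s0))^2)
}

hotelling_stat_cols <- function(X, Gmat) {
  apply(Gmat, 2L, function(g) {
    g1 <- g == 1
    hotelling_value(X, g1, sum(g1), sum(!g1))$t2
  })
}
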