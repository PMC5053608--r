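#' @keywords internal
gene_pvalues <- function(p, gene_ids, test_name) {
  structure(list(p = as.numeric(p), gene_ids = gene_ids,
                 test_name = test_name),
            class = "gene_pvalues")
}

#' @export
print.gene_pvalues <- function(x, ...) {
  cat(sprintf("gene_pvalues: %d genes, test = %s, min p = %.3g\n",
              length(x$p), x$test_name, min(x$p)))
  invisible(x)
}

# floor applied before any logarithm so ln(p) stays finite
P_FLOOR <- 1e-300

# Vectorised two-sample t-test p-values for every column of a group-1
# indicator matrix. X is genes x samples; Gmat is samples x (B+1) with 0/1
# membership of group 1 (column 1 is usually the observed labelling). Returns
# a genes x (B+1) matrix of p-values. Degenerate rows (zero variance in both
# groups) get p = 1 when the mean difference is also 0.
t_pvalue_matrix <- function(X, Gmat, alternative = "two.sided",
                            var_equal = TRUE) {
  n <- ncol(X)
  n1 <- colSums(Gmat)
  n2 <- n - n1
  S1 <- X %*% Gmat
  Q1 <- (X * X) %*% Gmat
  S <- rowSums(X)
  Q <- rowSums(X * X)
  m1 <- sweep(S1, 2, n1, "/")
  m2 <- sweep(S - S1, 2, n2, "/")
  ss1 <- Q1 - sweep(S1^2, 2, n1, "/")
  ss2 <- (Q - Q1) - sweep((S - S1)^2, 2, n2, "/")
  diff <- m1 - m2
  if (var_equal) {
    sp2 <- sweep(ss1 + ss2, 2, n1 + n2 - 2, "/")
    se <- sqrt(sweep(sp2, 2, 1 / n1 + 1 / n2, "*"))
    df <- matrix(n1 + n2 - 2, nrow(X), ncol(Gmat), byrow = TRUE)
  } else {
    v1 <- sweep(ss1, 2, n1 - 1, "/")
    v2 <- sweep(ss2, 2, n2 - 1, "/")
    a <- sweep(v1, 2, n1, "/")
    b <- sweep(v2, 2, n2, "/")
    se <- sqrt(a + b)
    df <- (a + b)^2 / (sweep(a^2, 2, n1 - 1, "/") + sweep(b^2, 2, n2 - 1, "/"))
  }
  tt <- diff / se
  p <- if (alternative == "two.sided") {
    2 * stats::pt(-abs(tt), df)
  } else if (alternative == "greater") {
    stats::pt(tt, df, lower.tail = FALSE)
  } else {
    stats::pt(tt, df)
  }
  degen <- !is.finite(tt)
  if (any(degen)) p[degen] <- ifelse(abs(diff[degen]) < .Machine$double.eps, 1, P_FLOOR)
  pmin(pmax(p, P_FLOOR), 1)
}

# Vectorised Wilcoxon rank-sum p-values (normal approximation with tie and
# continuity correction) for every column of a group-1 indicator matrix.
wilcoxon_pvalue_matrix <- function(X, Gmat) {
  n <- ncol(X)
  n1 <- colSums(Gmat)
  n2 <- n - n1
  R <- t(apply(X, 1L, rank))
  tiesum <- apply(X, 1L, function(x) {
    tt <- table(x)
    sum(tt^3 - tt)
  })
  W1 <- R %*% Gmat
  mu <- matrix(n1 * (n + 1) / 2, nrow(X), ncol(Gmat), byrow = TRUE)
  corr_fac <- (n + 1) - tiesum / (n * (n - 1))
  sig2 <- outer(corr_fac, n1 * n2 / 12)
  z <- (abs(W1 - mu) - 0.5) / sqrt(sig2)
  p <- 2 * stats::pnorm(-z)
  p[!is.finite(z)] <- 1  # all-tied gene: zero variance
  pmin(pmax(p, P_FLOOR), 1)
}

#' Per-gene two-sample t-test p-values
#'
#' Computes, for every gene, the two-sample t statistic between the two
#' phenotype groups and its p-value. The default is the pooled-variance
#' (Student) test with `n1 + n2 - 2` degrees of freedom; set
#' `var_equal = FALSE` for the Welch form. Genes with identical values in
#' both groups are degenerate and get p = 1 with a warning.
#'
#' @param mat An [expression_matrix()].
#' @param alternative `"two.sided"` (default), `"greater"` (group 1 mean
#'   larger) or `"less"`.
#' @param var_equal Pooled-variance t if `TRUE` (default), Welch otherwise.
#' @return A `gene_pvalues` object with elements `p`, `gene_ids`,
#'   `test_name`.
#' @export
#' @examples
#' mat <- expression_matrix(matrix(rnorm(40), 4, 10),
#'                          group_labels = rep(c("a", "b"), each = 5))
#' t_test_per_gene(mat)
t_test_per_gene <- function(mat, alternative = c("two.sided", "greater", "less"),
                            var_equal = TRUE) {
  alternative <- match.arg(alternative)
  g1 <- group1_mask(mat)
  G <- matrix(as.numeric(g1), ncol = 1L)
  X <- mat$values
  degen <- apply(X, 1L, function(x) stats::var(x[g1]) == 0 && stats::var(x[!g1]) == 0)
  p <- drop(t_pvalue_matrix(X, G, alternative, var_equal))
  if (any(degen)) {
    warning(sum(degen), " degenerate gene(s) with zero variance in both groups; p set to 1")
    p[degen] <- 1
  }
  gene_pvalues(p, mat$gene_ids, if (var_equal) "t" else "t_welch")
}

#' Per-gene Wilcoxon rank-sum p-values
#'
#' Two-sided rank-sum test per gene. With 20 or fewer samples in total and no
#' ties the exact null enumeration is used; otherwise the normal
#' approximation with tie and continuity correction. Genes whose values are
#' all tied get p = 1 with a warning.
#'
#' @inheritParams t_test_per_gene
#' @return A `gene_pvalues` object.
#' @export
wilcoxon_test_per_gene <- function(mat) {
  g1 <- group1_mask(mat)
  X <- mat$values
  n <- ncol(X)
  p <- vapply(seq_len(nrow(X)), function(i) {
    x <- X[i, g1]
    y <- X[i, !g1]
    if (length(unique(c(x, y))) == 1L) return(NA_real_)
    has_ties <- anyDuplicated(c(x, y)) > 0L
    suppressWarnings(stats::wilcox.test(
      x, y, exact = (n <= 20 && !has_ties), correct = TRUE)$p.value)
  }, numeric(1))
  if (anyNA(p)) {
    warning(sum(is.na(p)), " all-tied gene(s); p set to 1")
    p[is.na(p)] <- 1
  }
  gene_pvalues(pmin(pmax(p, P_FLOOR), 1), mat$gene_ids, "wilcoxon")
}
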