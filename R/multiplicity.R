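#' Benjamini-Hochberg step-up over a collection of set p-values
#'
#' Orders the p-values ascending and finds the largest index `k` with
#' `p_(k) < k * alpha / K_sets` (strict inequality; `K_sets` the number of
#' sets tested). All sets with index at or below `k` are retained; the
#' expected fraction of false positives among them is controlled at
#' `alpha`. Ties in p are ordered by set name so the retained prefix is
#' reproducible. Note the strict `<` differs from the common `<=`
#' formulation only when a p-value exactly equals its threshold.
#'
#' @param pvalues Named numeric vector of set p-values in `[0, 1]`.
#' @param alpha Target false discovery rate in (0, 1).
#' @return A list of class `fdr_result`: `set_names` (sorted by p),
#'   `p_sorted`, `alpha`, `k_star`, `retained`.
#' @export
#' @examples
#' benjamini_hochberg(c(a = .001, b = .02, c = .04), alpha = .05)
benjamini_hochberg <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0L) stop("no p-values supplied")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  if (is.null(names(pvalues)))
    names(pvalues) <- paste0("set", seq_along(pvalues))
  ord <- order(pvalues, names(pvalues))
  p_sorted <- pvalues[ord]
  Ksets <- length(pvalues)
  k <- seq_len(Ksets)
  pass <- p_sorted < k * alpha / Ksets
  k_star <- if (any(pass)) max(k[pass]) else 0L
  structure(list(set_names = names(p_sorted), p_sorted = unname(p_sorted),
                 alpha = alpha, k_star = as.integer(k_star),
                 retained = names(p_sorted)[seq_len(k_star)]),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("fdr_result: %d of %d sets retained at FDR %g\n",
              x$k_star, length(x$p_sorted), x$alpha))
  invisible(x)
}
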