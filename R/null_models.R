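#' Consolidated p-value of the classical Fisher statistic
#'
#' Upper-tail probability of the chi-squared distribution with `2K` degrees
#' of freedom, valid for the untruncated statistic (`p_min = 0`) on
#' independent genes.
#'
#' @param stat A `set_statistic` from [fisher_F()] with `p_min = 0`.
#' @return The consolidated p-value.
#' @export
#' @examples
#' chisq_set_pvalue(fisher_F(rep(.5, 10)))
chisq_set_pvalue <- function(stat) {
  stopifnot(inherits(stat, "set_statistic"))
  if (stat$method != "fisher") stop("chi-squared null applies to the Fisher statistic")
  if (!is.na(stat$p_min) && stat$p_min > 0)
    stop("use modified null: statistic was truncated at p_min > 0")
  chisq_tail(stat$value, stat$K)
}

chisq_tail <- function(F, K) stats::pchisq(F, df = 2 * K, lower.tail = FALSE)

#' Null distribution of the truncated Fisher statistic
#'
#' Under the null every gene's p-value is uniform on (0, 1), and the
#' truncated statistic `F = -2 * sum(log(max(U_k, p_min)))` no longer
#' follows a chi-squared distribution. Two representations are provided:
#'
#' * `"mc"` (default): Monte-Carlo draws of `K` uniforms pushed through the
#'   statistic, stored sorted. This mirrors how the distribution is
#'   constructed by simulation and is the representation used by the
#'   threshold solvers.
#' * `"analytic"`: the exact mixture form. The number of floored genes is
#'   Binomial(K, p_min), each contributing exactly `-2*log(p_min)`; the
#'   remaining genes contribute `-2*log(U)` with `U` uniform on
#'   `(p_min, 1)`, a truncated-exponential density convolved numerically by
#'   FFT. Used as the independent cross-check of the Monte-Carlo form.
#'
#' With `p_min = 0` both representations reduce to the chi-squared
#' distribution with `2K` degrees of freedom, which is then used directly.
#'
#' @param K Set size (number of genes).
#' @param p_min Truncation floor in `[0, 1)`.
#' @param n_draws Number of Monte-Carlo draws (ignored for `"analytic"`).
#' @param seed Integer seed for the Monte-Carlo draws.
#' @param representation `"mc"` or `"analytic"`.
#' @param grid_points Grid resolution per gene for the analytic convolution.
#' @return An object of class `modified_fisher_null`.
#' @export
build_modified_null <- function(K, p_min, n_draws = 1e6, seed = 1,
                                representation = c("mc", "analytic"),
                                grid_points = 4096) {
  representation <- match.arg(representation)
  if (p_min < 0 || p_min >= 1) stop("p_min must be in [0, 1)")
  K <- as.integer(K)
  out <- list(K = K, p_min = p_min, representation = representation,
              n_draws = NA_integer_, seed = NA_integer_)
  if (p_min == 0) {
    # untruncated: exact chi-squared(2K), no sampling needed
    out$representation <- "chisq"
    class(out) <- "modified_fisher_null"
    return(out)
  }
  if (representation == "mc") {
    n_draws <- as.integer(n_draws)
    set.seed(seed)
    draws <- numeric(n_draws)
    chunk <- 1e5L
    done <- 0L
    lp <- log(p_min)
    while (done < n_draws) {
      m <- min(chunk, n_draws - done)
      U <- matrix(stats::runif(K * m), K, m)
      draws[(done + 1L):(done + m)] <- -2 * colSums(log(pmax(U, p_min)))
      done <- done + m
    }
    out$draws <- sort(draws)
    out$n_draws <- n_draws
    out$seed <- as.integer(seed)
  } else {
    out <- c(out, analytic_mixture_cdf(K, p_min, grid_points))
    out$representation <- "analytic"
  }
  class(out) <- "modified_fisher_null"
  out
}

# Exact mixture CDF of the truncated Fisher statistic on a grid.
# One untruncated gene contributes y = -2 log(U), U ~ Unif(p_min, 1):
#   density f(y) = (1/2) exp(-y/2) / (1 - p_min) on [0, T], T = -2 log(p_min).
# j floored genes shift the sum by exactly j*T.
analytic_mixture_cdf <- function(K, p_min, grid_points) {
  T_ <- -2 * log(p_min)
  M <- as.integer(grid_points)          # grid points per gene-support [0, T]
  dt <- T_ / M
  N <- stats::nextn(K * M + M, 2)       # padded FFT length
  y <- (seq_len(N) - 1) * dt
  f <- ifelse(y <= T_, 0.5 * exp(-y / 2) / (1 - p_min), 0)
  phi <- stats::fft(f * dt)
  dens <- numeric(K * M + 1)
  w <- stats::dbinom(0:K, K, p_min)
  for (j in 0:K) {
    kk <- K - j                          # untruncated genes
    if (kk == 0L) {
      dens[j * M + 1] <- dens[j * M + 1] + w[j + 1] / dt
      next
    }
    dj <- Re(stats::fft(phi^kk, inverse = TRUE)) / (N * dt)
    dj <- pmax(dj[seq_len(kk * M + 1)], 0)
    idx <- (j * M + 1):(j * M + kk * M + 1)
    keep <- idx <= length(dens)
    dens[idx[keep]] <- dens[idx[keep]] + w[j + 1] * dj[keep]
  }
  cdf <- cumsum(dens) * dt
  cdf <- cdf / cdf[length(cdf)]
  list(grid = (0:(K * M)) * dt, cdf = cdf)
}

#' @export
print.modified_fisher_null <- function(x, ...) {
  cat(sprintf("modified_fisher_null: K = %d, p_min = %g, representation = %s%s\n",
              x$K, x$p_min, x$representation,
              if (!is.na(x$n_draws)) sprintf(" (%d draws)", x$n_draws) else ""))
  invisible(x)
}

null_upper_tail <- function(null, F) {
  switch(null$representation,
         chisq = chisq_tail(F, null$K),
         mc = {
           # count of draws >= F via the sorted vector
           n <- null$n_draws
           below <- findInterval(F - 1e-12, null$draws)
           (1 + (n - below)) / (1 + n)
         },
         analytic = {
           # evaluate the CDF half a grid step below F so the atom of
           # fully-floored draws at the maximum support stays in the tail
           dt <- null$grid[2] - null$grid[1]
           cdfF <- stats::approx(null$grid, null$cdf, xout = F - dt / 2,
                                 rule = 2)$y
           pmax(1 - cdfF, 0)
         })
}

null_quantile <- function(null, prob) {
  switch(null$representation,
         chisq = stats::qchisq(prob, 2 * null$K),
         mc = unname(stats::quantile(null$draws, prob, type = 7)),
         analytic = stats::approx(null$cdf, null$grid, xout = prob,
                                  rule = 2, ties = "ordered")$y)
}

#' Consolidated p-value under the truncated-Fisher null
#'
#' Upper-tail probability of the observed statistic under a null built by
#' [build_modified_null()] for the same `K` and `p_min`. The Monte-Carlo
#' representation returns `(1 + #(draws >= F)) / (1 + n_draws)`.
#'
#' @param stat A `set_statistic` from [fisher_F()].
#' @param null A `modified_fisher_null` with matching `K` and `p_min`.
#' @return The consolidated p-value.
#' @export
modified_set_pvalue <- function(stat, null) {
  stopifnot(inherits(stat, "set_statistic"), inherits(null, "modified_fisher_null"))
  if (stat$method != "fisher") stop("modified null applies to the Fisher statistic")
  if (stat$K != null$K) stop("set size K does not match the null (", stat$K,
                             " vs ", null$K, ")")
  pm <- if (is.na(stat$p_min)) 0 else stat$p_min
  if (!isTRUE(all.equal(pm, null$p_min))) stop("p_min does not match the null")
  null_upper_tail(null, stat$value)
}

#' Per-gene p-value needed by dominant genes to carry a set
#'
#' Solves for the common p-value `p` of `n_dominant` genes such that the
#' untruncated Fisher statistic of the set reaches the `alpha` critical
#' value when the remaining `K - n_dominant` genes sit at `p_rest`:
#' `-2*(n_dominant*log(p) + (K - n_dominant)*log(p_rest)) = qchisq(1-alpha, 2K)`.
#' Quantifies how few strongly significant genes suffice to make a whole
#' set significant under the classical (untruncated) statistic.
#'
#' @param K Set size.
#' @param n_dominant Number of dominant genes, between 1 and `K`.
#' @param alpha Target consolidated significance level.
#' @param p_rest p-value assumed for each remaining gene.
#' @return A list of class `threshold_result` with `p_single` (the solved
#'   p-value) and `attainable` (`FALSE` when the rest of the set already
#'   crosses the critical value, in which case `p_single = 1`).
#' @export
#' @examples
#' dominant_gene_threshold(10, 1)   # ~3.5e-6
#' dominant_gene_threshold(20, 3)   # ~1.2e-3
dominant_gene_threshold <- function(K, n_dominant, alpha = 0.01, p_rest = 0.5) {
  if (n_dominant < 1 || n_dominant > K) stop("n_dominant must lie in [1, K]")
  if (p_rest <= 0 || p_rest >= 1) stop("p_rest must be in (0, 1)")
  F_alpha <- stats::qchisq(1 - alpha, 2 * K)
  lp <- (-F_alpha / 2 - (K - n_dominant) * log(p_rest)) / n_dominant
  attainable <- lp < 0
  structure(list(K = as.integer(K), alpha = alpha, F_alpha = F_alpha,
                 n_dominant = as.integer(n_dominant), p_rest = p_rest,
                 p_single = if (attainable) exp(lp) else 1,
                 attainable = attainable),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("threshold_result: K =", x$K, ", alpha =", x$alpha)
  if (!is.null(x$p_single)) cat(", p_single =", signif(x$p_single, 3))
  if (!is.null(x$K_min)) cat(", K_min =", x$K_min)
  cat("\n")
  invisible(x)
}

#' Minimum number of floored genes for set significance
#'
#' Under the truncated statistic a single gene contributes at most
#' `-2*log(p_min)`, so several genes must reach the floor before the set
#' can cross its critical value. This returns the smallest `j` such that
#' `-2*(j*log(p_min) + (K - j)*log(p_rest)) > F_alpha`, with `F_alpha` the
#' `(1 - alpha)` quantile of the truncated-Fisher null. For `p_min = 0` a
#' single gene always suffices.
#'
#' @inheritParams dominant_gene_threshold
#' @param p_min Truncation floor.
#' @param null Optional prebuilt [build_modified_null()] for `(K, p_min)`;
#'   built on demand otherwise.
#' @param ... Passed to [build_modified_null()] when `null` is missing
#'   (e.g. `n_draws`, `seed`, `representation`).
#' @return A `threshold_result` with `K_min` (`NA` with
#'   `attainable = FALSE` if even `j = K` does not cross).
#' @export
minimum_genes_required <- function(K, p_min, alpha = 0.01, null = NULL,
                                   p_rest = 0.5, ...) {
  if (p_min == 0) {
    return(structure(list(K = as.integer(K), alpha = alpha,
                          F_alpha = stats::qchisq(1 - alpha, 2 * K),
                          p_min = 0, p_rest = p_rest, K_min = 1L,
                          attainable = TRUE),
                     class = "threshold_result"))
  }
  if (is.null(null)) null <- build_modified_null(K, p_min, ...)
  if (null$K != K || !isTRUE(all.equal(null$p_min, p_min)))
    stop("null was built for different (K, p_min)")
  F_alpha <- null_quantile(null, 1 - alpha)
  j <- seq_len(K)
  stat_j <- -2 * (j * log(p_min) + (K - j) * log(p_rest))
  ok <- stat_j > F_alpha
  K_min <- if (any(ok)) min(j[ok]) else NA_integer_
  structure(list(K = as.integer(K), alpha = alpha, F_alpha = F_alpha,
                 p_min = p_min, p_rest = p_rest, K_min = K_min,
                 attainable = any(ok)),
            class = "threshold_result")
}

#' Proportion of genes required for set significance over a grid
#'
#' Tabulates `K_min / K` from [minimum_genes_required()] over a grid of set
#' sizes and truncation floors; the proportion decreases with set size at a
#' fixed floor.
#'
#' @param K_list Integer vector of set sizes.
#' @param p_min_list Numeric vector of truncation floors.
#' @inheritParams minimum_genes_required
#' @return A data frame with columns `K`, `p_min`, `K_min`, `proportion`.
#' @export
required_proportion_curve <- function(K_list, p_min_list, alpha = 0.01, ...) {
  grid <- expand.grid(K = K_list, p_min = p_min_list)
  res <- mapply(function(K, pm) {
    r <- minimum_genes_required(K, pm, alpha, ...)
    c(K_min = r$K_min, proportion = r$K_min / K)
  }, grid$K, grid$p_min)
  cbind(grid, K_min = res["K_min", ], proportion = res["proportion", ])
}
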