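#' Configuration for the synthetic-data engine
#'
#' Bundles the generative parameters of the simulation studies: `K` genes
#' per set, group sizes `n1`/`n2`, group means `mu1`/`mu2` (in expression
#' units), common standard deviation `sigma`, inter-gene correlation `r`
#' (a constant in `[0, 1)` or `"mixed"`), the number of replicate datasets,
#' the permutation budget `B` and a master seed.
#'
#' @param K Genes per set.
#' @param n1,n2 Samples per phenotype group.
#' @param mu1,mu2 Group means; `mu2 != mu1` produces differential
#'   expression in every gene of the set.
#' @param sigma Common standard deviation (> 0).
#' @param r Inter-gene correlation: a value in `[0, 1)` or `"mixed"`.
#' @param n_datasets Replicate datasets for the study drivers.
#' @param B Permutations per replicate.
#' @param seed Master seed; every driver draws all its randomness from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(K = 20, n1 = 50, n2 = 50, mu1 = 0, mu2 = 0,
                       sigma = 1, r = 0, n_datasets = 1, B = 1000, seed = 1) {
  if (sigma <= 0) stop("sigma must be positive")
  if (!identical(r, "mixed")) {
    r <- as.numeric(r)
    if (r < 0 || r >= 1) stop("r must be in [0, 1) or \"mixed\"")
  }
  if (n_datasets < 1) stop("n_datasets must be >= 1")
  structure(list(K = as.integer(K), n1 = as.integer(n1), n2 = as.integer(n2),
                 mu1 = mu1, mu2 = mu2, sigma = sigma, r = r,
                 n_datasets = as.integer(n_datasets), B = as.integer(B),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# raw K x (n1+n2) matrix; assumes RNG state already set by the caller
sim_matrix_raw <- function(cfg) {
  n <- cfg$n1 + cfg$n2
  X <- matrix(stats::rnorm(cfg$K * n, sd = cfg$sigma), cfg$K, n)
  if (!identical(cfg$r, "mixed") && cfg$r > 0 || identical(cfg$r, "mixed")) {
    U <- correlation_cholesky(cfg$K, cfg$r)
    X <- crossprod(U, X)   # t(U) %*% Z has correlation R = t(U) U
  }
  X <- X + cfg$mu1
  if (cfg$mu2 != cfg$mu1)
    X[, (cfg$n1 + 1):n] <- X[, (cfg$n1 + 1):n] + (cfg$mu2 - cfg$mu1)
  X
}

# upper-triangular Cholesky factor of the gene-gene correlation matrix,
# eigen-repaired to the nearest positive-definite matrix when needed
correlation_cholesky <- function(K, r) {
  R <- if (identical(r, "mixed")) {
    idx <- seq_len(K)
    M <- 0.15 + 0.15 * sin(2 * pi * outer(idx, idx))
    M <- (M + t(M)) / 2
    diag(M) <- 1
    M
  } else {
    M <- matrix(r, K, K)
    diag(M) <- 1
    M
  }
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-6) {
    vals <- pmax(ev$values, 1e-6)
    R2 <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(R2))
    R2 <- R2 / outer(d, d)
    dev <- max(abs(R2 - R))
    if (dev > 0.05)
      warning("positive-definite repair changed the correlation matrix by up to ",
              signif(dev, 3))
    R <- R2
  }
  chol(R)
}

as_sim_expression <- function(X, cfg) {
  expression_matrix(X,
                    gene_ids = paste0("g", seq_len(nrow(X))),
                    sample_ids = paste0("s", seq_len(ncol(X))),
                    group_labels = rep(c("group1", "group2"), c(cfg$n1, cfg$n2)))
}

#' Simulate a null gene set
#'
#' `K` x `(n1 + n2)` iid normal expression values with identical means in
#' both groups (no differential expression, no inter-gene correlation).
#'
#' @param cfg A [sim_config()] with `r = 0` and `mu2 = mu1`.
#' @return An [expression_matrix()] with the first `n1` samples in group 1.
#' @export
generate_null_set <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!identical(cfg$r, "mixed") && cfg$r != 0)
    stop("null set generator requires r = 0; use generate_correlated_set")
  cfg2 <- cfg
  cfg2$mu2 <- cfg2$mu1
  set.seed(cfg$seed)
  as_sim_expression(sim_matrix_raw(cfg2), cfg)
}

#' Simulate a mean-shifted gene set
#'
#' As [generate_null_set()] but group-2 samples have mean `mu2`: every gene
#' of the set is differentially expressed by `mu2 - mu1`.
#'
#' @param cfg A [sim_config()]; `mu2` is the group-2 mean.
#' @return An [expression_matrix()].
#' @export
generate_shifted_set <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  as_sim_expression(sim_matrix_raw(cfg), cfg)
}

#' Simulate a gene set with correlated genes
#'
#' Inter-gene correlation is imposed by Cholesky-factoring the target
#' correlation matrix and applying the factor to iid normal draws sample by
#' sample. `r` constant gives a compound-symmetric matrix; `r = "mixed"`
#' uses `0.15 + 0.15*sin(2*pi*k1*k2)` over gene index pairs, symmetrised
#' and eigen-repaired (eigenvalues floored at 1e-6) before factoring. A
#' repair that moves any entry by more than .05 triggers a warning.
#'
#' @param cfg A [sim_config()] with `r` in `(0, 1)` or `"mixed"`.
#' @return An [expression_matrix()].
#' @export
generate_correlated_set <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  as_sim_expression(sim_matrix_raw(cfg), cfg)
}

method_label <- function(method, p_min) {
  ifelse(method == "fisher", sprintf("fisher(p_min=%g)", p_min), method)
}

# shared per-replicate engine: permutation p-value per requested method
replicate_perm_pvalues <- function(X, n1, B, methods, fisher_p_min,
                                   gene_test, alternative, s0) {
  n <- ncol(X)
  g1 <- rep(c(TRUE, FALSE), c(n1, n - n1))
  Gmat <- permutation_indicators(g1, B, seed = NULL)
  needs_p <- any(methods %in% c("fisher", "stouffer", "tail_strength", "ks"))
  P <- if (needs_p) perm_gene_pvalues(X, Gmat, gene_test, alternative) else NULL
  out <- numeric(0)
  labels <- character(0)
  pp <- function(v) (sum(v[-1L] >= v[1L]) + 1) / (B + 1)
  for (m in methods) {
    if (m == "fisher") {
      for (pm in fisher_p_min) {
        out <- c(out, pp(fisher_stat_cols(P, pm)))
        labels <- c(labels, method_label("fisher", pm))
      }
    } else {
      v <- perm_set_stats(X, P, Gmat, m, s0 = s0)
      out <- c(out, pp(v))
      labels <- c(labels, m)
    }
  }
  names(out) <- labels
  out
}

rejection_study <- function(cfg, methods, fisher_p_min, alpha_level,
                            gene_test, alternative, s0) {
  set.seed(cfg$seed)
  first <- NULL
  rej <- NULL
  for (i in seq_len(cfg$n_datasets)) {
    X <- sim_matrix_raw(cfg)
    p <- replicate_perm_pvalues(X, cfg$n1, cfg$B, methods, fisher_p_min,
                                gene_test, alternative, s0)
    if (is.null(rej)) rej <- stats::setNames(numeric(length(p)), names(p))
    rej <- rej + (p < alpha_level)
  }
  data.frame(method = names(rej),
             fraction_rejected = unname(rej) / cfg$n_datasets,
             n1 = cfg$n1, n2 = cfg$n2, K = cfg$K,
             n_datasets = cfg$n_datasets, B = cfg$B,
             mu_delta = cfg$mu2 - cfg$mu1,
             row.names = NULL)
}

#' Power study across set-level methods
#'
#' Simulates `n_datasets` replicate gene sets with a group-2 mean shift and
#' reports, per method, the fraction of replicates whose permutation
#' p-value falls below `alpha_level`. Within a replicate all methods share
#' the same permutations, so method comparisons are free of permutation
#' budget noise.
#'
#' @param cfg A [sim_config()]; `mu2 - mu1` is the effect size (default
#'   study: `mu2 = .15`).
#' @param methods Subset of the six set statistics.
#' @param fisher_p_min Truncation floor(s) evaluated for the Fisher rows.
#' @param alpha_level Set-level rejection threshold for "power".
#' @param gene_test,alternative Per-gene test configuration.
#' @param s0 SAM-GS fudge constant.
#' @return Data frame with one row per method: `method`,
#'   `fraction_rejected` (the power), and the study parameters.
#' @export
run_power_study <- function(cfg, methods = "fisher", fisher_p_min = 0,
                            alpha_level = 0.05, gene_test = "t",
                            alternative = "two.sided", s0 = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  rejection_study(cfg, methods, fisher_p_min, alpha_level, gene_test,
                  alternative, s0)
}

#' Type-I error study across set-level methods
#'
#' As [run_power_study()] but with the group-2 shift removed: the reported
#' fraction of rejections estimates the type-I error at `alpha_level`.
#'
#' @inheritParams run_power_study
#' @return Data frame as in [run_power_study()].
#' @export
run_type1_study <- function(cfg, methods = "fisher", fisher_p_min = 0,
                            alpha_level = 0.05, gene_test = "t",
                            alternative = "two.sided", s0 = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  cfg$mu2 <- cfg$mu1
  rejection_study(cfg, methods, fisher_p_min, alpha_level, gene_test,
                  alternative, s0)
}

#' Correlation of set-level p-values between methods
#'
#' Simulates replicate null gene sets and computes each method's
#' permutation p-value from a shared permutation budget per replicate; the
#' result is the Pearson correlation matrix of the methods' p-values over
#' replicates. Highly correlated methods rank the same datasets as
#' significant.
#'
#' @inheritParams run_power_study
#' @return The methods x methods Pearson correlation matrix, with the
#'   underlying p-value matrix attached as attribute `"pvalues"`.
#' @export
run_correlation_study <- function(cfg, methods = c("fisher", "samgs", "stouffer"),
                                  fisher_p_min = 0, gene_test = "t",
                                  alternative = "two.sided", s0 = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  cfg$mu2 <- cfg$mu1
  rows <- vector("list", cfg$n_datasets)
  for (i in seq_len(cfg$n_datasets)) {
    X <- sim_matrix_raw(cfg)
    rows[[i]] <- replicate_perm_pvalues(X, cfg$n1, cfg$B, methods,
                                        fisher_p_min, gene_test,
                                        alternative, s0)
  }
  pmat <- do.call(rbind, rows)
  r <- stats::cor(pmat)
  attr(r, "pvalues") <- pmat
  r
}

#' Fit the p-value extrapolation law on correlated null data
#'
#' Simulates `n_datasets` replicate null datasets with inter-gene
#' correlation `cfg$r`. Each replicate contributes one pair: the
#' independence-null p-value of its observed Fisher statistic (`p_uncorr`,
#' chi-squared for `p_min = 0`, truncated-Fisher null otherwise) and its
#' permutation p-value over `cfg$B` relabellings (`p_corr`). Ordinary least
#' squares on `log(p_corr) ~ log(p_uncorr)` pooled over replicates returns
#' the power-law coefficients `(m, b)` of `p_corr = b * p_uncorr^m`.
#'
#' Per-gene p-values here are one-sided in the t statistic: a monotone
#' gene-level transform preserves the inter-gene correlation inside the
#' combined statistic, which is what makes the fitted law informative about
#' correlation strength (an even, two-sided transform cancels the leading
#' correlation term and the fitted slope collapses towards 1).
#'
#' @param cfg A [sim_config()] with the correlation level in `r`.
#' @param p_min Truncation floor for the Fisher statistic.
#' @param alternative Sidedness of the per-gene test (see above).
#' @param fit_range Optional `p_corr` interval to restrict the fit to.
#' @param null Optional prebuilt truncated-Fisher null for `p_min > 0`.
#' @return A `regression_fit` with extra elements `r`, `n_datasets`, `B`,
#'   and the pooled pairs as attribute `"pairs"`.
#' @export
run_regression_study <- function(cfg, p_min = 0, alternative = "greater",
                                 fit_range = NULL, null = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (p_min > 0 && is.null(null))
    null <- build_modified_null(cfg$K, p_min, seed = cfg$seed)
  set.seed(cfg$seed)
  cfg$mu2 <- cfg$mu1
  g1 <- rep(c(TRUE, FALSE), c(cfg$n1, cfg$n2))
  pu <- pc <- numeric(cfg$n_datasets)
  for (i in seq_len(cfg$n_datasets)) {
    X <- sim_matrix_raw(cfg)
    Gmat <- permutation_indicators(g1, cfg$B, seed = NULL)
    P <- t_pvalue_matrix(X, Gmat, alternative)
    F <- fisher_stat_cols(P, p_min)
    pu[i] <- if (p_min > 0) null_upper_tail(null, F[1L]) else chisq_tail(F[1L], cfg$K)
    pc[i] <- (sum(F[-1L] >= F[1L]) + 1) / (cfg$B + 1)
  }
  keep <- if (is.null(fit_range)) rep(TRUE, length(pc)) else
    pc >= fit_range[1] & pc <= fit_range[2]
  fit <- stats::lm(log(pc[keep]) ~ log(pu[keep]))
  out <- regression_fit(unname(stats::coef(fit)[2]),
                        exp(unname(stats::coef(fit)[1])),
                        sum(keep),
                        if (is.null(fit_range)) c(0, 1) else fit_range)
  out$r <- cfg$r
  out$n_datasets <- cfg$n_datasets
  out$B <- cfg$B
  attr(out, "pairs") <- data.frame(p_uncorr = pu, p_corr = pc)
  out
}
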