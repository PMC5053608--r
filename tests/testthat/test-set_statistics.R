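test_that("Fisher statistic evaluates its closed-form cases", {
  expect_equal(fisher_F(rep(1, 3))$value, 0)
  expect_equal(fisher_F(rep(.5, 10))$value, -2 * 10 * log(.5), tolerance = 1e-10)
  expect_equal(fisher_F(rep(.5, 10))$value, 13.8629, tolerance = 1e-4)
  # truncation floors the 1e-6 at .01
  expect_equal(fisher_F(c(1e-6, rep(.5, 9)), p_min = .01)$value,
               -2 * (log(.01) + 9 * log(.5)), tolerance = 1e-10)
  expect_equal(fisher_F(c(1e-6, rep(.5, 9)), p_min = .01)$value, 21.687,
               tolerance = 1e-3)
  expect_error(fisher_F(numeric(0)), "empty")
  expect_error(fisher_F(rep(.5, 3), p_min = 1), "p_min")
})

test_that("Fisher statistic is monotone, order-invariant, and truncation-bounded", {
  set.seed(7)
  for (i in 1:20) {
    p <- runif(12)
    expect_equal(fisher_F(sample(p))$value, fisher_F(p)$value, tolerance = 1e-12)
    # decreasing any p_k increases F
    q <- p; q[3] <- q[3] / 2
    expect_gt(fisher_F(q)$value, fisher_F(p)$value)
    # truncated statistic never exceeds the untruncated one
    pm <- runif(1, 0, .5)
    expect_lte(fisher_F(p, pm)$value, fisher_F(p, 0)$value + 1e-12)
    if (all(p >= pm))
      expect_equal(fisher_F(p, pm)$value, fisher_F(p, 0)$value, tolerance = 1e-12)
  }
})

test_that("Stouffer statistic matches its normal-quantile identities", {
  expect_equal(stouffer_Z(rep(.5, 7))$value, 0, tolerance = 1e-10)
  s <- stouffer_Z(.05)
  expect_equal(s$value, qnorm(.95), tolerance = 1e-4)
  expect_equal(s$consolidated_p, .05, tolerance = 1e-10)
  expect_equal(stouffer_Z(rep(.05, 4))$value, 2 * qnorm(.95), tolerance = 1e-10)
  expect_warning(stouffer_Z(c(1, .5)), "clamped")
})

test_that("Tail Strength matches its direct formula", {
  K <- 9
  expect_equal(tail_strength((1:K) / (K + 1))$value, 0, tolerance = 1e-12)
  expect_equal(tail_strength(.25)$value, .5, tolerance = 1e-12)
  # all p = 1, K = 2: (1/2) * ((1 - 3) + (1 - 3/2))
  expect_equal(tail_strength(c(1, 1))$value, -1.25, tolerance = 1e-12)
})

test_that("K-S departure statistic matches hand evaluation", {
  expect_equal(ks_statistic(.3)$value, .7, tolerance = 1e-12)
  expect_equal(ks_statistic(c(.5, .5))$value, .5, tolerance = 1e-12)
  K <- 8
  expect_equal(ks_statistic((seq_len(K) - .5) / K)$value, 1 / (2 * K),
               tolerance = 1e-12)
})

test_that("all six statistics are invariant to gene order", {
  mat <- make_mat(K = 6, n1 = 8, n2 = 8, seed = 5)
  p <- t_test_per_gene(mat)$p
  set <- gene_set("all", mat$gene_ids)
  perm <- sample(6)
  mat2 <- expression_matrix(mat$values[perm, ], mat$gene_ids[perm],
                            mat$sample_ids, mat$group_labels)
  for (f in list(fisher_F, stouffer_Z, tail_strength, ks_statistic))
    expect_equal(f(p[perm])$value, f(p)$value, tolerance = 1e-12)
  expect_equal(samgs_statistic(mat2, set)$value,
               samgs_statistic(mat, set)$value, tolerance = 1e-10)
  expect_equal(hotelling_T2(mat2, set)$value,
               hotelling_T2(mat, set)$value, tolerance = 1e-8)
})

test_that("SAM-GS reduces to the squared pooled t for one gene and s0 = 0", {
  mat <- two_group_mat(c(1.2, 3.4, 2.2, 0.8), c(2.5, 4.1, 3.3))
  set <- gene_set("one", "g1")
  d2 <- samgs_statistic(mat, set, s0 = 0)$value
  tt <- t.test(c(1.2, 3.4, 2.2, 0.8), c(2.5, 4.1, 3.3), var.equal = TRUE)$statistic
  expect_equal(d2, unname(tt^2), tolerance = 1e-10)
})

test_that("SAM-GS with s0 = 0 is scale-invariant, zero for identical groups", {
  mat <- make_mat(K = 5, n1 = 6, n2 = 6, seed = 11)
  set <- gene_set("all", mat$gene_ids)
  scaled <- mat
  scaled$values <- mat$values * 3.7
  expect_equal(samgs_statistic(scaled, set)$value,
               samgs_statistic(mat, set)$value, tolerance = 1e-10)
  sym <- mat
  sym$values <- cbind(mat$values[, 1:6], mat$values[, 1:6])
  expect_equal(samgs_statistic(sym, set)$value, 0, tolerance = 1e-20)
})

test_that("Hotelling T2 reduces to t^2 in 1-D and is affine invariant", {
  mat <- two_group_mat(c(1.2, 3.4, 2.2, 0.8), c(2.5, 4.1, 3.3, 1.0))
  expect_equal(hotelling_T2(mat, gene_set("one", "g1"))$value,
               unname(t.test(c(1.2, 3.4, 2.2, 0.8), c(2.5, 4.1, 3.3, 1.0),
                             var.equal = TRUE)$statistic^2),
               tolerance = 1e-10)
  # invertible linear map of the 3-gene sample vectors leaves T2 unchanged
  mat3 <- make_mat(K = 3, n1 = 7, n2 = 7, delta = .5, seed = 13)
  set3 <- gene_set("all", mat3$gene_ids)
  A <- matrix(c(2, .3, 0, -.5, 1, .2, .1, 0, 1.5), 3, 3)
  matA <- expression_matrix(A %*% mat3$values, mat3$gene_ids,
                            mat3$sample_ids, mat3$group_labels)
  expect_equal(hotelling_T2(matA, set3)$value, hotelling_T2(mat3, set3)$value,
               tolerance = 1e-8)
  # zero mean difference
  sym <- make_mat(K = 3, n1 = 5, n2 = 5, seed = 2)
  sym$values <- cbind(sym$values[, 1:5], sym$values[, 1:5])
  expect_equal(hotelling_T2(sym, gene_set("all", sym$gene_ids))$value, 0,
               tolerance = 1e-18)
})

test_that("Hotelling falls back to the pseudo-inverse when K exceeds the df", {
  mat <- make_mat(K = 12, n1 = 4, n2 = 4, seed = 17)   # K = 12 > n - 2 = 6
  res <- hotelling_T2(mat, gene_set("all", mat$gene_ids))
  expect_true(is.finite(res$value))
  expect_lt(res$rank, 12)
})

test_that("untruncated Fisher draws follow chi-squared with 2K df", {
  set.seed(31)
  K <- 10
  draws <- -2 * colSums(log(matrix(runif(K * 10000), K)))
  d <- suppressWarnings(ks.test(draws, pchisq, df = 2 * K)$statistic)
  expect_lt(d, .02)
})

test_that("genes absent from the matrix are dropped and counted", {
  mat <- make_mat(K = 4, seed = 23)
  set <- gene_set("s", c("g1", "g2", "nope1", "nope2"))
  res <- samgs_statistic(mat, set)
  expect_equal(res$genes_found, 2L)
  expect_equal(res$K, 4L)
  expect_error(samgs_statistic(mat, gene_set("s2", c("x", "y"))), "empty")
})
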