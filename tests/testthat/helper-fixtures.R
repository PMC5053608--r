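# small deterministic fixtures shared across test files

make_mat <- function(K = 6, n1 = 5, n2 = 5, delta = 0, seed = 1, sigma = 1) {
  set.seed(seed)
  n <- n1 + n2
  X <- matrix(rnorm(K * n, sd = sigma), K, n)
  if (delta != 0) X[, (n1 + 1):n] <- X[, (n1 + 1):n] + delta
  expression_matrix(X, paste0("g", seq_len(K)), paste0("s", seq_len(n)),
                    rep(c("A", "B"), c(n1, n2)))
}

two_group_mat <- function(group1, group2, gene_id = "g1") {
  vals <- matrix(c(group1, group2), nrow = 1)
  expression_matrix(vals, gene_id,
                    paste0("s", seq_len(length(group1) + length(group2))),
                    rep(c("A", "B"), c(length(group1), length(group2))))
}

write_gmt_lines <- function(lines) {
  path <- tempfile(fileext = ".gmt")
  writeLines(lines, path)
  path
}

extdata <- function(file) system.file("extdata", file, package = "fisherset")
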