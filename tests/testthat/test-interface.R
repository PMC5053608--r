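test_that("GMT parsing follows the format contract", {
  path <- write_gmt_lines(c("SET1\tdesc\tG1\tG2",
                            "SET2\tother desc\tG2\tG3\tG4"))
  col <- read_gmt(path)
  expect_length(col$sets, 2)
  expect_identical(col$sets$SET1$gene_ids, c("G1", "G2"))
  expect_identical(col$sets$SET2$description, "other desc")
  # duplicate gene within a line: dedup with warning
  expect_warning(col2 <- read_gmt(write_gmt_lines("SET1\td\tG1\tG1")),
                 "duplicate gene ids")
  expect_identical(col2$sets$SET1$gene_ids, "G1")
  # malformed line names its number
  expect_error(read_gmt(write_gmt_lines(c("SET1\td\tG1", "SET2\tnogenes"))),
               "line 2")
  # duplicate set names across lines
  expect_error(read_gmt(write_gmt_lines(c("S\td\tG1\tG2", "S\td\tG3\tG4"))),
               "duplicate set name")
})

test_that("match_sets drops absent genes and flags unusable sets", {
  mat <- make_mat(K = 5, seed = 31)   # genes g1..g5
  path <- write_gmt_lines(c("FULL\td\tg1\tg2\tg3",
                            "PARTIAL\td\tg4\tg5\tnope1\tnope2",
                            "GONE\td\tnope3\tnope4",
                            "SINGLETON\td\tg1\tnope5"))
  expect_warning(m <- match_sets(read_gmt(path), mat), "skipped")
  expect_identical(m$sets$FULL$gene_ids, c("g1", "g2", "g3"))
  expect_false(m$sets$FULL$skipped)
  expect_equal(m$sets$PARTIAL$genes_found, 2L)
  expect_equal(m$sets$PARTIAL$n_annotated, 4L)
  expect_true(m$sets$GONE$skipped)
  expect_true(m$sets$SINGLETON$skipped)
})

test_that("run_analysis ranks a shifted set above a null set, deterministically", {
  set.seed(91)
  X <- matrix(rnorm(20 * 24), 20, 24)
  X[1:8, 13:24] <- X[1:8, 13:24] + 1.5
  mat <- expression_matrix(X, paste0("g", 1:20), paste0("s", 1:24),
                           rep(c("ctl", "case"), each = 12))
  path <- write_gmt_lines(c(paste(c("SHIFTED", "d", paste0("g", 1:8)), collapse = "\t"),
                            paste(c("NULL_SET", "d", paste0("g", 9:20)), collapse = "\t")))
  res <- run_analysis(mat, path, B = 200, seed = 5, extrapolate = FALSE)
  expect_s3_class(res, "fisherset_results")
  expect_lt(res$p_reported[res$set == "SHIFTED"],
            res$p_reported[res$set == "NULL_SET"])
  expect_true(res$bh_retained[res$set == "SHIFTED"])
  # byte-identical rerun under the same seed
  res2 <- run_analysis(mat, path, B = 200, seed = 5, extrapolate = FALSE)
  expect_identical(res, res2)
  f1 <- tempfile(); f2 <- tempfile()
  write_results_tsv(res, f1); write_results_tsv(res2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("extrapolation engages when the observed statistic beats all permutations", {
  set.seed(92)
  K <- 30
  U <- chol(matrix(.3, K, K) + diag(1 - .3, K))
  X <- crossprod(U, matrix(rnorm(K * 40), K, 40))
  X[, 21:40] <- X[, 21:40] + 1.0
  mat <- expression_matrix(X, paste0("g", 1:K), paste0("s", 1:40),
                           rep(c("a", "b"), each = 20))
  path <- write_gmt_lines(paste(c("BIGSET", "d", paste0("g", 1:K)), collapse = "\t"))
  res <- run_analysis(mat, path, B = 2000, seed = 6, extrapolate = TRUE)
  expect_false(is.na(res$p_extrapolated))
  expect_lt(res$p_reported, 1 / 2001)
  expect_equal(res$p_reported, res$p_extrapolated)
})

test_that("the end-to-end pipeline runs on the synthetic text fixtures", {
  mat <- read_expression(extdata("synthetic_expression.tsv"),
                         extdata("synthetic_labels.tsv"))
  res <- run_analysis(mat, extdata("synthetic_sets.gmt"), B = 300,
                      p_min = .05, gene_test = "wilcoxon", seed = 7,
                      extrapolate = FALSE)
  # the PARTIAL set keeps its two matched genes, so all three sets run
  expect_setequal(res$set, c("SYNTHETIC_SHIFTED_SET", "SYNTHETIC_NULL_SET",
                             "SYNTHETIC_PARTIAL_SET"))
  expect_lt(res$p_reported[res$set == "SYNTHETIC_SHIFTED_SET"], .05)
  expect_gt(res$p_reported[res$set == "SYNTHETIC_NULL_SET"], .05)
  expect_equal(res$genes_found[res$set == "SYNTHETIC_PARTIAL_SET"], 2L)
})

test_that("the CLI dispatcher produces schema-stable tables", {
  out <- tempfile(fileext = ".tsv")
  fisherset_cli(c("thresholds", "--K", "10", "--p-min", "0.05,0",
                  "--n-draws", "1000000", "--seed", "3", "--out", out))
  tab <- read.delim(out)
  expect_identical(names(tab), c("K", "p_min", "K_min", "proportion"))
  expect_equal(tab$K_min[tab$p_min == 0], 1)
  expect_equal(tab$K_min[tab$p_min == .05], 5)

  out2 <- tempfile(fileext = ".tsv")
  fisherset_cli(c("simulate-type1", "--K", "5", "--n1", "10", "--n2", "10",
                  "--n-datasets", "30", "--B", "49", "--seed", "4",
                  "--out", out2))
  tab2 <- read.delim(out2)
  expect_identical(names(tab2)[1:2], c("method", "fraction_rejected"))
  # same seed, same bytes
  out3 <- tempfile(fileext = ".tsv")
  fisherset_cli(c("simulate-type1", "--K", "5", "--n1", "10", "--n2", "10",
                  "--n-datasets", "30", "--B", "49", "--seed", "4",
                  "--out", out3))
  expect_identical(readLines(out2), readLines(out3))

  expr <- extdata("synthetic_expression.tsv")
  lab <- extdata("synthetic_labels.tsv")
  gmt <- extdata("synthetic_sets.gmt")
  out4 <- tempfile(fileext = ".tsv")
  suppressWarnings(fisherset_cli(c("analyze", "--expr", expr, "--labels", lab,
                                   "--gmt", gmt, "--B", "99", "--seed", "1",
                                   "--out", out4)))
  tab4 <- read.delim(out4)
  expect_true(all(c("set", "statistic", "p_perm", "p_reported", "bh_retained")
                  %in% names(tab4)))
  expect_error(fisherset_cli("nonsense"), "unknown subcommand")
  expect_error(fisherset_cli(c("analyze", "--expr")), "needs a value")
  expect_error(fisherset_cli(c("analyze", "--B", "10")), "--gmt|--expr")
})
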