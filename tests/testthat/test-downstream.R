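test_that("identify_domains: trivial, separable, deterministic", {
  set.seed(8)
  Z <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 100), 10, 2))
  one <- identify_domains(Z, k = 1)
  expect_equal(one$labels, rep(0L, 20))

  two <- identify_domains(Z, k = 2, seed = 4)
  truth <- rep(0:1, each = 10)
  expect_equal(adjusted_rand_index(two, truth), 1.0)
  expect_true(all(two$labels >= 0 & two$labels < 2))

  expect_identical(identify_domains(Z, 2, seed = 4)$labels, two$labels)
  expect_error(identify_domains(Z, k = 21), "k must be")
})

test_that("evaluate_mse is the mean squared row norm", {
  expect_equal(evaluate_mse(matrix(c(1, 1), 1), matrix(c(1, 1), 1)), 0)
  expect_equal(evaluate_mse(matrix(c(1, 1), 1), matrix(c(0, 1), 1)), 1.0)
  expect_equal(evaluate_mse(matrix(c(1, 3), 2), matrix(c(0, 0), 2)), 5.0)
  a <- matrix(rnorm(12), 3); b <- matrix(rnorm(12), 3)
  expect_equal(evaluate_mse(a, b), evaluate_mse(b, a))
  expect_equal(evaluate_mse(a, a), 0)
  expect_error(evaluate_mse(a, matrix(0, 2, 2)), "shape")
})

test_that("ARI: hand example, invariances, pair-count oracle", {
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(5, 5, 2, 2)), 1.0)

  set.seed(13)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    a <- sample(0:2, n, replace = TRUE)
    b <- sample(0:2, n, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), ari_pair_oracle(a, b),
                 tolerance = 1e-12,
                 label = paste("a =", paste(a, collapse = ""), "b =",
                               paste(b, collapse = "")))
    # label-permutation invariance
    expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(a, 7 - b))
  }
  # ARI == 1 iff the partitions are identical
  expect_lt(adjusted_rand_index(c(0, 0, 1, 1), c(0, 0, 0, 1)), 1)
})

test_that("evaluate_clustering computes what the inputs permit", {
  set.seed(14)
  f <- rbind(matrix(rnorm(30, 0, 0.2), 15, 2), matrix(rnorm(30, 5, 0.2), 15, 2))
  lab <- rep(0:1, each = 15)
  rep_full <- evaluate_clustering(lab, truth = lab, features = f)
  expect_equal(rep_full$ari, 1.0)
  expect_true(rep_full$silhouette > 0.9 && rep_full$silhouette <= 1)
  expect_true(rep_full$davies_bouldin >= 0 && rep_full$davies_bouldin < 0.2)

  expect_null(evaluate_clustering(lab, truth = lab)$silhouette)
  expect_warning(r1 <- evaluate_clustering(rep(0, 30), features = f), "single")
  expect_null(r1$silhouette)
  expect_null(r1$ari)
})

test_that("wilcoxon p-values match enumeration and exact references", {
  # exhaustive independent oracle, group sizes <= 6, with and without ties
  set.seed(15)
  for (rep in 1:20) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(0:4, nx, replace = TRUE)       # ties likely
    y <- sample(0:4, ny, replace = TRUE)
    expect_equal(wilcoxon_rank_sum(x, y), wilcoxon_perm_oracle(x, y),
                 tolerance = 1e-12,
                 label = paste("x =", paste(x, collapse = ","),
                               "y =", paste(y, collapse = ",")))
  }
  # agrees with R's exact test when there are no ties
  for (rep in 1:10) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1))
    expect_equal(wilcoxon_rank_sum(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # spec'd worked examples
  expect_equal(wilcoxon_rank_sum(c(4, 4, 4), c(0, 0, 0)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(4, 4, 4, 4, 4), c(0, 0, 0, 0, 0)), 2 / 252)
})

test_that("differential expression applies the three filters", {
  # 5 vs 5: p = 2/252, single gene, BH leaves it; reported
  X <- matrix(c(rep(4, 5), rep(0, 5)), 10, 1)
  colnames(X) <- "gA"
  lab <- rep(c(0L, 1L), each = 5)
  deg <- differential_expression(X, lab)
  expect_equal(nrow(deg), 1)
  expect_equal(deg$gene, "gA")
  expect_equal(deg$domain, 0L)
  expect_equal(deg$p, 2 / 252)
  expect_equal(deg$fdr, 2 / 252)              # single test: FDR == p
  expect_equal(deg$pct_in, 1)

  # 3 vs 3: p = 0.1 > 0.05; correctly rejected
  X3 <- matrix(c(rep(4, 3), rep(0, 3)), 6, 1)
  deg3 <- differential_expression(X3, rep(c(0L, 1L), each = 3))
  expect_equal(nrow(deg3), 0)

  # a gene identical in and out of the domain is never reported
  Xn <- cbind(X, gB = rep(2, 10))
  degn <- differential_expression(Xn, lab)
  expect_false("gB" %in% degn$gene)

  # FDR values are valid probabilities
  set.seed(16)
  Xr <- matrix(abs(rnorm(20 * 8)), 20, 8)
  labr <- rep(0:1, each = 10)
  degr <- differential_expression(Xr, labr, pct_min = 0, lfc_min = 0,
                                  fdr_max = 1)
  expect_true(all(degr$fdr >= 0 & degr$fdr <= 1))
  expect_true(all(degr$p >= 0 & degr$p <= 1))

  expect_error(differential_expression(X, c(rep(0L, 9), 5L)), "domain.*5")
})

test_that("downstream writers produce readable artifacts", {
  dir <- withr::local_tempdir()
  X <- matrix(c(rep(4, 5), rep(0, 5)), 10, 1)
  colnames(X) <- "gA"
  lab <- rep(c(0L, 1L), each = 5)
  deg <- differential_expression(X, lab)
  write_deg_tsv(deg, file.path(dir, "deg.tsv"))
  back <- read.delim(file.path(dir, "deg.tsv"))
  expect_equal(back$gene, "gA")

  write_labels_tsv(lab, sprintf("s%d", 1:10), file.path(dir, "labels.tsv"))
  lb <- read.delim(file.path(dir, "labels.tsv"))
  expect_equal(lb$domain, lab)

  rep1 <- evaluate_clustering(lab, truth = lab)
  write_report_json(rep1, file.path(dir, "report.json"))
  expect_equal(jsonlite::read_json(file.path(dir, "report.json"))$ari, 1.0)
})
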