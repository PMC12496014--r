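test_that("noise-free, dropout-free simulation reproduces clean data", {
  sim <- simulate_multiview(sim_config(n_spots = 60, n_genes = 30,
                                       n_clusters = 4, noise_var = 0,
                                       morph_noise_var = 0, dropout_rate = 0,
                                       seed = 5))
  expect_equal(as.matrix(sim$dataset$expression),
               sim$truth$clean_expression, ignore_attr = TRUE)
  expect_equal(evaluate_mse(sim$truth$clean_expression,
                            as.matrix(sim$dataset$expression)), 0)
  expect_equal(sim$dataset$morphology, sim$truth$clean_morphology,
               ignore_attr = TRUE)
})

test_that("cluster sizes are balanced and runs are deterministic", {
  cfg <- sim_config(n_spots = 100, n_genes = 20, n_clusters = 7, seed = 2)
  sim <- simulate_multiview(cfg)
  sizes <- table(sim$truth$labels)
  expect_equal(length(sizes), 7L)
  expect_true(max(sizes) - min(sizes) <= 1)
  expect_true(all(abs(sizes - 100 / 7) <= 1))

  sim2 <- simulate_multiview(cfg)
  expect_identical(as.matrix(sim$dataset$expression),
                   as.matrix(sim2$dataset$expression))
  expect_identical(sim$truth$labels, sim2$truth$labels)
  expect_identical(sim$dataset$coords, sim2$dataset$coords)

  sim3 <- simulate_multiview(sim_config(n_spots = 100, n_genes = 20,
                                        n_clusters = 7, seed = 3))
  expect_false(identical(as.matrix(sim$dataset$expression),
                         as.matrix(sim3$dataset$expression)))
})

test_that("clusters are spatially contiguous patches", {
  sim <- simulate_multiview(sim_config(n_spots = 144, n_genes = 10,
                                       n_clusters = 6, seed = 1))
  # each spot's spatial nearest neighbor set is dominated by its own cluster
  idx <- mvsrt:::knn_indices(sim$dataset$coords, 4)
  lab <- sim$truth$labels
  same <- mean(vapply(seq_len(nrow(idx)), function(i)
    mean(lab[idx[i, ]] == lab[i]), numeric(1)))
  expect_gt(same, 0.75)
})

test_that("add_noise is calibrated and seeded", {
  m <- matrix(0, 400, 300)                     # 1.2e5 entries
  expect_identical(add_noise(m, 0, seed = 1), m)
  out <- add_noise(m, 0.5, seed = 1)
  expect_identical(out, add_noise(m, 0.5, seed = 1))
  expect_equal(mean((out - m)^2), 0.5, tolerance = 0.02)
  expect_error(add_noise(m, -1), "variance")
})

test_that("add_dropout is calibrated, seeded, and absorbing on zeros", {
  m <- matrix(1, 400, 300)
  expect_identical(add_dropout(m, 0, seed = 1), m)
  out <- add_dropout(m, 0.3, seed = 2)
  expect_identical(out, add_dropout(m, 0.3, seed = 2))
  expect_equal(mean(out == 0), 0.3, tolerance = 0.02 * 0.3 + 0.005)
  expect_true(all(out %in% c(0, 1)))
  mz <- m; mz[1:100, ] <- 0
  outz <- add_dropout(mz, 0.4, seed = 3)
  expect_true(all(outz[1:100, ] == 0))
  expect_error(add_dropout(m, 1), "rate")
})

test_that("merge_clusters partitions labels and regenerates clean views", {
  sim <- simulate_multiview(sim_config(n_spots = 150, n_genes = 40,
                                       n_clusters = 15, seed = 4))
  # identity merge: labels unchanged up to renaming
  same <- merge_clusters(sim$truth, 15, seed = 1)
  expect_equal(adjusted_rand_index(same$labels, sim$truth$labels), 1.0)

  merged <- merge_clusters(sim$truth, 6, seed = 1)
  expect_equal(length(unique(merged$labels)), 6L)
  # every original cluster maps to exactly one merged label
  map <- table(sim$truth$labels, merged$labels)
  expect_true(all(rowSums(map > 0) == 1))
  # merged clusters share a centroid: within a merged label, spots from
  # different original clusters now have identical cluster means in the
  # clean views up to their retained deviations
  expect_equal(nrow(merged$centroids), 6L)
  expect_equal(dim(merged$clean_expression), dim(sim$truth$clean_expression))
  expect_error(merge_clusters(sim$truth, 20), "target_k")
})

test_that("zero-noise simulation is separable by plain K-means", {
  # default simulator config (900 spots, 500 genes, 15 clusters); a generous
  # restart budget so the check measures generator separability, not K-means
  # local optima
  aris <- vapply(0:4, function(s) {
    sim <- simulate_multiview(sim_config(noise_var = 0, seed = s))
    lab <- identify_domains(sim$truth$clean_expression, k = 15, seed = s,
                            n_init = 50)
    adjusted_rand_index(lab, sim$truth$labels)
  }, numeric(1))
  expect_gte(median(aris), 0.95)
})

test_that("benchmark trends: MSE rises with noise, ARI falls with dropout", {
  # a fixed cheap denoiser (the graph filter itself) sees non-decreasing
  # median MSE as the injected noise grows
  mse_at <- function(nv) {
    vapply(0:2, function(s) {
      sim <- simulate_multiview(sim_config(n_spots = 150, n_genes = 60,
                                           n_clusters = 6, noise_var = nv,
                                           seed = s))
      g <- build_knn_affinity(sim$dataset$coords, 6)
      den <- laplacian_filter(as.matrix(sim$dataset$expression), g, 2)$values
      evaluate_mse(sim$truth$clean_expression, den)
    }, numeric(1))
  }
  med <- vapply(c(0, 0.3, 0.6, 0.9), function(nv) median(mse_at(nv)), numeric(1))
  expect_true(all(diff(med) >= 0))

  ari_at <- function(dr) {
    vapply(0:2, function(s) {
      sim <- simulate_multiview(sim_config(n_spots = 150, n_genes = 60,
                                           n_clusters = 6, noise_var = 0.3,
                                           dropout_rate = dr, seed = s))
      lab <- identify_domains(as.matrix(sim$dataset$expression), k = 6,
                              seed = s)
      adjusted_rand_index(lab, sim$truth$labels)
    }, numeric(1))
  }
  meda <- vapply(c(0, 0.3, 0.6), function(dr) median(ari_at(dr)), numeric(1))
  expect_true(all(diff(meda) <= 1e-9))
})
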