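#' Simulation configuration
#'
#' Parameters of the multiview simulator.  Clustered latent structure is
#' shared between the transcript and morphology views; the transcript view
#' is perturbed with additive Gaussian noise (variance swept in benchmarks
#' over 0-0.9) and independent entrywise dropout, while morphology receives
#' fixed-level noise.  Loadings are scaled so clean expression entries have
#' roughly unit variance, making `noise_var` directly comparable to signal.
#'
#' @param n_spots number of spots (default 900).
#' @param n_genes transcript features (default 500).
#' @param d_morph morphology features (default 128).
#' @param n_clusters latent clusters / spatial domains (default 15).
#' @param latent_dim shared latent dimension (default 10).
#' @param noise_var transcript noise variance in `[0, 0.9]` (default 0.3).
#' @param morph_noise_var morphology noise variance (default 0.1).
#' @param dropout_rate entrywise zeroing probability in `[0, 1)` (default 0).
#' @param seed RNG seed (default 0).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_spots = 900, n_genes = 500, d_morph = 128,
                       n_clusters = 15, latent_dim = 10, noise_var = 0.3,
                       morph_noise_var = 0.1, dropout_rate = 0, seed = 0) {
  if (n_clusters > n_spots) stop("n_clusters must be <= n_spots")
  if (noise_var < 0 || morph_noise_var < 0) stop("variances must be >= 0")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  structure(list(n_spots = as.integer(n_spots), n_genes = as.integer(n_genes),
                 d_morph = as.integer(d_morph),
                 n_clusters = as.integer(n_clusters),
                 latent_dim = as.integer(latent_dim),
                 noise_var = noise_var, morph_noise_var = morph_noise_var,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Additive Gaussian noise
#'
#' @param clean numeric matrix.
#' @param variance noise variance, >= 0.
#' @param seed RNG seed.
#' @return `clean + N(0, variance)` elementwise.
#' @export
add_noise <- function(clean, variance, seed = 0) {
  if (variance < 0) stop("variance must be >= 0")
  clean <- as.matrix(clean)
  if (variance == 0) return(clean)
  clean + with_seed(seed, matrix(stats::rnorm(length(clean),
                                              sd = sqrt(variance)),
                                 nrow(clean), ncol(clean)))
}

#' Entrywise dropout
#'
#' Sets each entry independently to 0 with probability `rate`; existing
#' zeros are unchanged.
#'
#' @param mat numeric matrix.
#' @param rate dropout probability in `[0, 1)`.
#' @param seed RNG seed.
#' @return Matrix with dropped entries zeroed.
#' @export
add_dropout <- function(mat, rate, seed = 0) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  mat <- as.matrix(mat)
  if (rate == 0) return(mat)
  mask <- with_seed(seed, matrix(stats::runif(length(mat)) >= rate,
                                 nrow(mat), ncol(mat)))
  mat * mask
}

# serpentine grid order: spatially contiguous strips when chunked
serpentine_grid <- function(n) {
  side <- ceiling(sqrt(n))
  gx <- integer(0); gy <- integer(0)
  for (row in seq_len(side)) {
    cols <- seq_len(side)
    if (row %% 2 == 0) cols <- rev(cols)
    gx <- c(gx, cols); gy <- c(gy, rep(row, side))
  }
  cbind(x = gx[seq_len(n)], y = gy[seq_len(n)])
}

balanced_sizes <- function(n, k) {
  base <- n %/% k
  sizes <- rep(base, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- base + 1
  sizes
}

#' Simulate a multiview SRT dataset with ground truth
#'
#' Draws `n_clusters` latent centroids (standard Gaussian in
#' `latent_dim` dimensions), per-spot latents as centroid plus
#' within-cluster Gaussian scatter (sd 0.3), and maps them through
#' independent random loading matrices to produce clean transcript and
#' morphology views that share the same cluster structure.  Spots are laid
#' out on a jittered grid in serpentine order and clusters occupy
#' contiguous, balanced strips (each within one spot of `n_spots /
#' n_clusters`), so domains are spatially coherent.  The observed
#' expression is clean + Gaussian(`noise_var`) followed by dropout; observed
#' morphology is clean + Gaussian(`morph_noise_var`).  Deterministic given
#' `config$seed`.
#'
#' The returned dataset carries continuous (possibly negative) values and is
#' flagged `normalized = TRUE`; the count-based preprocessing chain does not
#' apply to it.
#'
#' @param config a [sim_config()].
#' @return List with `dataset` (an [srt_dataset()], `truth_labels` set) and
#'   `truth` (a `simulation_truth`: `clean_expression`, `clean_morphology`,
#'   `labels`, `config`, plus the latent pieces needed by
#'   [merge_clusters()]).
#' @export
simulate_multiview <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_spots; k <- config$n_clusters; d <- config$latent_dim
  parts <- with_seed(config$seed, {
    centroids <- matrix(stats::rnorm(k * d), k, d)
    sizes <- balanced_sizes(n, k)
    order_k <- sample.int(k)                # random cluster order along the strip
    labels <- rep(order_k, times = sizes[order_k]) - 1L
    dev <- matrix(stats::rnorm(n * d, sd = 0.3), n, d)
    load_e <- matrix(stats::rnorm(d * config$n_genes, sd = 1 / sqrt(d)),
                     d, config$n_genes)
    load_m <- matrix(stats::rnorm(d * config$d_morph, sd = 1 / sqrt(d)),
                     d, config$d_morph)
    grid <- serpentine_grid(n)
    coords <- grid + matrix(stats::runif(2 * n, -0.15, 0.15), n, 2)
    list(centroids = centroids, labels = labels, dev = dev,
         load_e = load_e, load_m = load_m, coords = coords)
  })
  latents <- parts$centroids[parts$labels + 1L, , drop = FALSE] + parts$dev
  clean_e <- latents %*% parts$load_e
  clean_m <- latents %*% parts$load_m
  obs_e <- add_noise(clean_e, config$noise_var, seed = config$seed + 1L)
  obs_e <- add_dropout(obs_e, config$dropout_rate, seed = config$seed + 2L)
  obs_m <- add_noise(clean_m, config$morph_noise_var, seed = config$seed + 3L)
  spot_ids <- sprintf("spot_%04d", seq_len(n))
  gene_ids <- sprintf("gene_%04d", seq_len(config$n_genes))
  ds <- srt_dataset(expression = obs_e, coords = parts$coords,
                    spot_ids = spot_ids, gene_ids = gene_ids,
                    morphology = obs_m, truth_labels = parts$labels,
                    normalized = TRUE)
  truth <- structure(list(clean_expression = clean_e,
                          clean_morphology = clean_m,
                          labels = parts$labels, config = config,
                          centroids = parts$centroids, deviations = parts$dev,
                          load_e = parts$load_e, load_m = parts$load_m),
                     class = "simulation_truth")
  list(dataset = ds, truth = truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("simulation_truth:", nrow(x$clean_expression), "spots,",
      ncol(x$clean_expression), "genes,",
      length(unique(x$labels)), "clusters\n")
  invisible(x)
}

#' Randomly merge simulated clusters
#'
#' Partitions the current cluster ids at random into `target_k` groups and
#' relabels spots accordingly.  Clean matrices are regenerated so merged
#' clusters literally share a centroid (the mean of the merged centroids) in
#' both the transcript and the morphology view, while each spot keeps its
#' original within-cluster deviation.
#'
#' @param truth a `simulation_truth`.
#' @param target_k desired cluster count, `1 <= target_k <=` current count.
#' @param seed RNG seed for the random grouping.
#' @return A new `simulation_truth` with `target_k` clusters.
#' @export
merge_clusters <- function(truth, target_k, seed = 0) {
  stopifnot(inherits(truth, "simulation_truth"))
  k <- nrow(truth$centroids)
  if (target_k < 1 || target_k > k)
    stop("target_k must be in [1, ", k, "]")
  group_of <- with_seed(seed, {
    perm <- sample.int(k)
    sizes <- balanced_sizes(k, target_k)
    g <- integer(k)
    g[perm] <- rep(seq_len(target_k), times = sizes)
    g
  })
  new_centroids <- do.call(rbind, lapply(seq_len(target_k), function(g) {
    colMeans(truth$centroids[group_of == g, , drop = FALSE])
  }))
  new_labels <- group_of[truth$labels + 1L] - 1L
  latents <- new_centroids[new_labels + 1L, , drop = FALSE] + truth$deviations
  cfg <- truth$config
  cfg$n_clusters <- as.integer(target_k)
  structure(list(clean_expression = latents %*% truth$load_e,
                 clean_morphology = latents %*% truth$load_m,
                 labels = new_labels, config = cfg,
                 centroids = new_centroids, deviations = truth$deviations,
                 load_e = truth$load_e, load_m = truth$load_m),
            class = "simulation_truth")
}
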