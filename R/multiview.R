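# k-nearest-neighbour indices (self excluded), distance ties broken by lower
# row index; returns an n x k integer matrix.
knn_indices <- function(features, k, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  features <- as.matrix(features)
  if (!all(is.finite(features))) stop("features contain non-finite values")
  n <- nrow(features)
  if (k < 1) stop("k must be >= 1")
  if (k >= n) stop("k (", k, ") must be smaller than the number of points (", n, ")")
  if (metric == "euclidean") {
    D <- as.matrix(stats::dist(features))
  } else {
    nrm <- sqrt(rowSums(features^2))
    nrm[nrm == 0] <- 1
    D <- 1 - tcrossprod(features / nrm)
  }
  diag(D) <- Inf
  idx <- matrix(0L, n, k)
  ord_key <- seq_len(n)
  for (i in seq_len(n)) idx[i, ] <- order(D[i, ], ord_key)[seq_len(k)]
  idx
}

#' Binary KNN affinity graph
#'
#' Builds the directed k-nearest-neighbour graph over the rows of `features`
#' (self excluded, distance ties broken by lower spot index) and symmetrizes
#' it by union: an edge is present if either endpoint selects the other.
#' The adjacency is sparse with entries in `{0, 1}`, zero diagonal.
#'
#' @param features spots x d numeric matrix (coordinates or morphology).
#' @param k neighbor count, `1 <= k < n`.
#' @param metric `"euclidean"` (default) or `"cosine"`.
#' @param view label stored on the graph (`"spatial"`, `"morphology"`, ...).
#' @return An `affinity_graph` with fields `adjacency`, `k`, `metric`, `view`.
#' @export
build_knn_affinity <- function(features, k, metric = c("euclidean", "cosine"),
                               view = "spatial") {
  metric <- match.arg(metric)
  idx <- knn_indices(features, k, metric)
  n <- nrow(idx)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k), j = as.vector(t(idx)),
                            x = 1, dims = c(n, n))
  A <- A + Matrix::t(A)
  A@x <- rep(1, length(A@x))       # union symmetrization, binary entries
  structure(list(adjacency = methods::as(A, "CsparseMatrix"),
                 k = as.integer(k), metric = metric, view = view),
            class = "affinity_graph")
}

#' @export
print.affinity_graph <- function(x, ...) {
  cat("affinity_graph (", x$view, "): ", nrow(x$adjacency), " spots, k = ",
      x$k, ", ", x$metric, ", ", length(x$adjacency@x), " edges\n", sep = "")
  invisible(x)
}

# dense {0,1} adjacency from an affinity_graph or matrix
adjacency_dense <- function(g) {
  A <- if (inherits(g, "affinity_graph")) g$adjacency else g
  A <- as.matrix(A)
  if (!all(A %in% c(0, 1))) stop("adjacency must be binary")
  A
}

#' Graph low-pass (Laplacian) filter
#'
#' Smooths a spots x features signal over a spot graph by applying `t` steps
#' of the self-loop renormalized propagation operator
#' \deqn{H = \tilde D^{-1/2} (A + I) \tilde D^{-1/2},}
#' where \eqn{\tilde D} is the degree matrix of \eqn{A + I}.  `H` is
#' `I - L_sym(A + I)`, i.e. the complement of a normalized Laplacian, hence a
#' low-pass filter: it attenuates signal components that disagree between
#' graph neighbors (high graph frequencies) while preserving smooth ones.
#' `t = 0` (or a `NULL` graph) returns the input unchanged.
#'
#' @param Y spots x features numeric matrix (the expression view).
#' @param graph an `affinity_graph` over the same spots, or `NULL`.
#' @param t non-negative integer filter order (default 2).
#' @return A `filtered_expression` object; `$values` holds the smoothed
#'   matrix, same shape as `Y`.
#' @export
laplacian_filter <- function(Y, graph, t = 2) {
  Y <- as.matrix(Y)
  if (t < 0 || t != round(t)) stop("t must be a non-negative integer")
  view <- "none"
  if (!is.null(graph) && t > 0) {
    A <- if (inherits(graph, "affinity_graph")) graph$adjacency else
      methods::as(Matrix::Matrix(graph, sparse = TRUE), "CsparseMatrix")
    if (length(A@x) && !all(A@x %in% c(0, 1)))
      stop("adjacency must be binary")
    if (nrow(A) != nrow(Y))
      stop("graph has ", nrow(A), " spots but Y has ", nrow(Y), " rows")
    view <- if (inherits(graph, "affinity_graph")) graph$view else "custom"
    n <- nrow(Y)
    At <- A + Matrix::Diagonal(n)
    dinv <- 1 / sqrt(Matrix::rowSums(At))
    H <- Matrix::Diagonal(x = dinv) %*% At %*% Matrix::Diagonal(x = dinv)
    for (i in seq_len(t)) Y <- as.matrix(H %*% Y)
  }
  structure(list(values = Y, filter_order = as.integer(t), graph_view = view),
            class = "filtered_expression")
}

#' @export
print.filtered_expression <- function(x, ...) {
  cat("filtered_expression:", nrow(x$values), "x", ncol(x$values),
      "(t =", x$filter_order, ", graph =", x$graph_view, ")\n")
  invisible(x)
}

# coerce filtered_expression or matrix to a plain matrix
as_values <- function(x) {
  if (inherits(x, "filtered_expression")) x$values else as.matrix(x)
}

#' Deterministic fallback patch-feature extractor
#'
#' Returns an extractor callable (patch batch -> feature batch) implementing
#' the pluggable-extractor contract without any pretrained weights: each
#' flattened patch is intensity-normalized (centered, unit variance) and
#' passed through a fixed random projection drawn once from `seed`.  Useful
#' for tests and for pipelines where no CNN backbone is available; swap in a
#' real backbone by passing any function with the same signature to
#' [extract_morphology()].
#'
#' @param d_m output feature dimension (default 128).
#' @param seed seed for the projection matrix (default 0).
#' @return A function mapping an n x p patch matrix to an n x d_m feature
#'   matrix.
#' @export
fallback_extractor <- function(d_m = 128, seed = 0) {
  proj <- NULL
  function(patches) {
    patches <- as.matrix(patches)
    p <- ncol(patches)
    if (is.null(proj)) {
      proj <<- with_seed(seed, matrix(stats::rnorm(p * d_m), p, d_m) / sqrt(p))
    }
    if (nrow(proj) != p)
      stop("patch dimension ", p, " does not match extractor input ", nrow(proj))
    mu <- rowMeans(patches)
    sd <- sqrt(rowMeans((patches - mu)^2))
    ((patches - mu) / (sd + 1e-8)) %*% proj
  }
}

#' Extract per-spot morphology features from a histology raster
#'
#' Crops a `patch_px` x `patch_px` window centered on each spot (patches
#' extending past the image border are zero-padded) and passes the batch of
#' flattened patches to `extractor`.  The image is an in-memory numeric array
#' `H x W` or `H x W x C`; decoding PNG/TIFF files is left to the caller.
#'
#' @param image numeric array, `H x W` (grayscale) or `H x W x C`.
#' @param coords spots x 2 matrix of (x = column, y = row) pixel positions.
#' @param patch_px even patch side length in pixels (default 64).
#' @param extractor callable patch-batch -> feature-batch; defaults to
#'   [fallback_extractor()].
#' @return spots x d_m feature matrix.
#' @export
extract_morphology <- function(image, coords, patch_px = 64,
                               extractor = fallback_extractor()) {
  if (patch_px %% 2 != 0) stop("patch_px must be even")
  dm <- dim(image)
  if (is.null(dm) || length(dm) < 2) stop("image must be a 2-D or 3-D array")
  H <- dm[1]; W <- dm[2]; C <- if (length(dm) == 3) dm[3] else 1L
  img <- array(as.numeric(image), dim = c(H, W, C))
  coords <- as.matrix(coords)
  n <- nrow(coords)
  half <- patch_px / 2
  patches <- matrix(0, n, patch_px * patch_px * C)
  for (i in seq_len(n)) {
    cx <- round(coords[i, 1]); cy <- round(coords[i, 2])
    rows <- (cy - half + 1):(cy + half)
    cols <- (cx - half + 1):(cx + half)
    ok_r <- rows >= 1 & rows <= H
    ok_c <- cols >= 1 & cols <= W
    patch <- array(0, dim = c(patch_px, patch_px, C))
    if (any(ok_r) && any(ok_c))
      patch[which(ok_r), which(ok_c), ] <- img[rows[ok_r], cols[ok_c], , drop = FALSE]
    patches[i, ] <- as.vector(patch)
  }
  feats <- extractor(patches)
  feats <- as.matrix(feats)
  if (nrow(feats) != n)
    stop("extractor returned ", nrow(feats), " rows for ", n, " patches")
  if (anyNA(feats)) stop("extractor produced NA features")
  feats
}
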