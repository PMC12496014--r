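#' Read a 10x Visium / Space Ranger directory
#'
#' Looks for `matrix.mtx[.gz]`, `barcodes.tsv[.gz]`, `features.tsv[.gz]` and a
#' tissue-position table (`tissue_positions.csv` v2 header, or the headerless
#' v1 `tissue_positions_list.csv`) in `path`, including under a
#' `filtered_feature_bc_matrix/` or `spatial/` subdirectory.  The count matrix
#' is returned oriented spots x genes regardless of on-disk orientation
#' (Space Ranger stores genes x barcodes; orientation is detected by matching
#' a dimension to the barcode count).  Spots flagged `in_tissue = 0` are
#' dropped.  Coordinates are (`pxl_col_in_fullres`, `pxl_row_in_fullres`).
#'
#' @param path directory containing the Space Ranger outputs.
#' @return An [srt_dataset()] with raw counts (`normalized = FALSE`).
#' @export
load_visium <- function(path) {
  find1 <- function(names, what) {
    cand <- unlist(lapply(c("", "filtered_feature_bc_matrix", "spatial"),
                          function(d) file.path(path, d, names)))
    hit <- cand[file.exists(cand)]
    if (length(hit) == 0)
      stop("missing file in Visium directory '", path, "': expected one of ",
           paste(names, collapse = ", "), " (", what, ")")
    hit[[1]]
  }
  mtx_f <- find1(c("matrix.mtx", "matrix.mtx.gz"), "count matrix")
  bc_f  <- find1(c("barcodes.tsv", "barcodes.tsv.gz"), "barcode table")
  ft_f  <- find1(c("features.tsv", "features.tsv.gz", "genes.tsv", "genes.tsv.gz"),
                 "feature table")
  pos_f <- find1(c("tissue_positions.csv", "tissue_positions.csv.gz",
                   "tissue_positions_list.csv", "tissue_positions_list.csv.gz"),
                 "tissue position table")

  counts <- Matrix::readMM(mtx_f)
  barcodes <- readLines(if (grepl("\\.gz$", bc_f)) gzfile(bc_f) else bc_f)
  feats <- utils::read.delim(if (grepl("\\.gz$", ft_f)) gzfile(ft_f) else ft_f,
                             header = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(feats[[1]])

  nb <- length(barcodes)
  if (ncol(counts) == nb && nrow(counts) == length(gene_ids)) {
    counts <- Matrix::t(counts)               # genes x barcodes on disk
  } else if (nrow(counts) == nb && ncol(counts) == length(gene_ids)) {
    # already spots x genes
  } else if (ncol(counts) == nb) {
    counts <- Matrix::t(counts)
  } else if (nrow(counts) != nb) {
    stop("barcode count mismatch: matrix is ", nrow(counts), " x ", ncol(counts),
         " but there are ", nb, " barcodes")
  }
  if (ncol(counts) != length(gene_ids))
    stop("feature count mismatch: matrix has ", ncol(counts),
         " genes but feature table has ", length(gene_ids))

  v1 <- grepl("tissue_positions_list", pos_f)
  pos <- utils::read.csv(if (grepl("\\.gz$", pos_f)) gzfile(pos_f) else pos_f,
                         header = !v1, stringsAsFactors = FALSE)
  if (v1) {
    colnames(pos) <- c("barcode", "in_tissue", "array_row", "array_col",
                       "pxl_row_in_fullres", "pxl_col_in_fullres")
  }
  need <- c("barcode", "in_tissue", "pxl_row_in_fullres", "pxl_col_in_fullres")
  if (!all(need %in% colnames(pos)))
    stop("tissue position table lacks columns: ",
         paste(setdiff(need, colnames(pos)), collapse = ", "))
  idx <- match(barcodes, pos$barcode)
  if (anyNA(idx))
    stop("barcode count mismatch: ", sum(is.na(idx)),
         " matrix barcodes absent from the position table")
  pos <- pos[idx, ]
  keep <- pos$in_tissue == 1
  counts <- counts[keep, , drop = FALSE]
  pos <- pos[keep, , drop = FALSE]
  srt_dataset(expression = counts,
              coords = cbind(pos$pxl_col_in_fullres, pos$pxl_row_in_fullres),
              spot_ids = pos$barcode, gene_ids = gene_ids,
              normalized = FALSE)
}

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.tsv(\\.gz)?$", path)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

as_numeric_table <- function(df, path) {
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("non-numeric cell in ", path, " at row ", bad[1], " (spot '",
         ids[bad[1]], "'), column ", bad[2] + 1)
  }
  list(ids = ids, m = m)
}

#' Read generic expression/coordinate (and optional morphology) tables
#'
#' Supports imaging-based platforms (STARmap, osmFISH) and any spots x genes
#' CSV/TSV export.  The expression table has gene ids as header and spot ids
#' in the first column; the coordinate table has matching spot ids plus two
#' numeric columns.  Rows are aligned by spot id in expression order; spots
#' present only in the coordinate (or morphology) table are ignored.
#'
#' @param expr_path expression table path (.csv/.tsv, optionally gzipped).
#' @param coords_path coordinate table path.
#' @param morph_path optional morphology feature table path.
#' @param normalized logical; set `TRUE` if the table already holds
#'   normalized (possibly negative) values.
#' @return An [srt_dataset()].
#' @export
load_tables <- function(expr_path, coords_path, morph_path = NULL,
                        normalized = FALSE) {
  for (p in c(expr_path, coords_path, morph_path))
    if (!file.exists(p)) stop("missing file: ", p)
  ex <- as_numeric_table(read_delim_auto(expr_path), expr_path)
  if (anyDuplicated(ex$ids))
    stop("duplicate spot ids in ", expr_path)
  co <- as_numeric_table(read_delim_auto(coords_path), coords_path)
  if (anyDuplicated(co$ids))
    stop("duplicate spot ids in ", coords_path)
  if (ncol(co$m) < 2)
    stop("coordinate table must have 2 numeric columns, found ", ncol(co$m))
  idx <- match(ex$ids, co$ids)
  if (anyNA(idx))
    stop("spots missing coordinates: ",
         paste(utils::head(ex$ids[is.na(idx)], 5), collapse = ", "))
  morph <- NULL
  if (!is.null(morph_path)) {
    mo <- as_numeric_table(read_delim_auto(morph_path), morph_path)
    midx <- match(ex$ids, mo$ids)
    if (anyNA(midx))
      stop("spots missing morphology features: ",
           paste(utils::head(ex$ids[is.na(midx)], 5), collapse = ", "))
    morph <- mo$m[midx, , drop = FALSE]
  }
  gene_ids <- colnames(ex$m)
  srt_dataset(expression = ex$m, coords = co$m[idx, 1:2, drop = FALSE],
              spot_ids = ex$ids, gene_ids = gene_ids,
              morphology = morph, normalized = normalized)
}

#' Remove lowly detected genes
#'
#' Drops genes with a nonzero count in fewer than `min_cells` spots, keeping
#' gene order otherwise.  The spot set is unchanged.  Applied to raw counts
#' before normalization.
#'
#' @param ds raw-count `srt_dataset`.
#' @param min_cells minimum number of spots with a nonzero count (default 10).
#' @return Filtered `srt_dataset`.
#' @export
filter_genes <- function(ds, min_cells = 10) {
  stopifnot(inherits(ds, "srt_dataset"))
  if (min_cells < 0) stop("min_cells must be >= 0")
  if (ds$normalized) stop("filter_genes expects raw counts (normalized flag is TRUE)")
  ncells <- if (methods::is(ds$expression, "sparseMatrix"))
    Matrix::colSums(ds$expression != 0) else colSums(ds$expression != 0)
  keep <- ncells >= min_cells
  if (!any(keep))
    warning("all ", length(keep), " genes fall below min_cells = ", min_cells)
  srt_dataset(expression = ds$expression[, keep, drop = FALSE],
              coords = ds$coords, spot_ids = ds$spot_ids,
              gene_ids = ds$gene_ids[keep], morphology = ds$morphology,
              truth_labels = ds$truth_labels, normalized = FALSE)
}

#' Library-size normalization and log-transform
#'
#' Scales every spot's counts to sum to `target_sum`, then applies natural
#' `log1p` elementwise.  All-zero spots cannot be scaled and are dropped
#' first with a warning.
#'
#' @param ds raw-count `srt_dataset`.
#' @param target_sum library size after scaling (default 1e4).
#' @return Normalized `srt_dataset` (`normalized = TRUE`).
#' @export
normalize_log <- function(ds, target_sum = 1e4) {
  stopifnot(inherits(ds, "srt_dataset"))
  if (ds$normalized) stop("dataset is already normalized (double normalization)")
  if (target_sum <= 0) stop("target_sum must be positive")
  ex <- ds$expression
  rs <- if (methods::is(ex, "sparseMatrix")) Matrix::rowSums(ex) else rowSums(ex)
  zero <- rs == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " all-zero spot(s) before normalization")
    ex <- ex[!zero, , drop = FALSE]
    rs <- rs[!zero]
  }
  keep <- !zero
  if (methods::is(ex, "sparseMatrix")) {
    ex <- Matrix::Diagonal(x = target_sum / rs) %*% ex
    ex <- methods::as(ex, "CsparseMatrix")
    ex@x <- log1p(ex@x)
  } else {
    ex <- ex * (target_sum / rs)
    ex <- log1p(ex)
  }
  srt_dataset(expression = ex, coords = ds$coords[keep, , drop = FALSE],
              spot_ids = ds$spot_ids[keep], gene_ids = ds$gene_ids,
              morphology = if (is.null(ds$morphology)) NULL else
                ds$morphology[keep, , drop = FALSE],
              truth_labels = if (is.null(ds$truth_labels)) NULL else
                ds$truth_labels[keep],
              normalized = TRUE)
}

#' Spatial neighborhood augmentation
#'
#' Concatenates each spot's expression with the mean expression of its `k`
#' spatial nearest neighbors (self excluded), weighted as
#' `[sqrt(1-lam) * X, sqrt(lam) * N(X)]`, doubling the feature count.  This
#' is the neighborhood-mean core of BANKSY-style augmentation; `lam` trades
#' own expression against microenvironment.
#'
#' @param ds normalized `srt_dataset`.
#' @param lam neighborhood weight in `[0, 1]` (default 0.2).
#' @param k number of spatial neighbors (default 6, the Visium hex ring).
#' @return spots x (2 * genes) matrix.
#' @export
banksy_augment <- function(ds, lam = 0.2, k = 6) {
  stopifnot(inherits(ds, "srt_dataset"))
  if (lam < 0 || lam > 1) stop("lam must be in [0, 1]")
  if (!ds$normalized) stop("banksy_augment expects a normalized dataset")
  n <- nrow(ds$coords)
  if (k >= n) stop("k (", k, ") must be smaller than the number of spots (", n, ")")
  X <- expr_dense(ds)
  idx <- knn_indices(ds$coords, k)
  NX <- matrix(0, n, ncol(X))
  for (i in seq_len(n)) NX[i, ] <- colMeans(X[idx[i, ], , drop = FALSE])
  out <- cbind(sqrt(1 - lam) * X, sqrt(lam) * NX)
  colnames(out) <- c(ds$gene_ids, paste0(ds$gene_ids, "_nbr"))
  rownames(out) <- ds$spot_ids
  out
}
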