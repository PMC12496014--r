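#' SRT dataset container
#'
#' Bundles the three views of a spatially resolved transcriptomics (SRT)
#' experiment: the expression matrix (spots x genes), the spot coordinates
#' (spots x 2) and, optionally, per-spot morphology features extracted from a
#' histology image.  Raw counts are non-negative; after [normalize_log()] the
#' matrix is real-valued and the `normalized` flag is set.
#'
#' @param expression spots x genes matrix (base matrix or `Matrix` sparse).
#' @param coords spots x 2 numeric matrix of spatial coordinates.
#' @param spot_ids character vector of unique spot identifiers.
#' @param gene_ids character vector of unique gene identifiers.
#' @param morphology optional spots x d_m numeric matrix of morphology features.
#' @param truth_labels optional integer vector of ground-truth domain labels.
#' @param normalized logical; `TRUE` once library-size normalization and
#'   log-transform have been applied.
#' @return An object of class `srt_dataset`.
#' @export
srt_dataset <- function(expression, coords, spot_ids, gene_ids,
                        morphology = NULL, truth_labels = NULL,
                        normalized = FALSE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(expression)
  if (length(spot_ids) != n)
    stop("spot_ids length (", length(spot_ids), ") != expression rows (", n, ")")
  if (anyDuplicated(spot_ids))
    stop("duplicate spot ids: ", paste(unique(spot_ids[duplicated(spot_ids)]), collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (length(gene_ids) != ncol(expression))
    stop("gene_ids length != expression columns")
  if (nrow(coords) != n || ncol(coords) != 2)
    stop("coords must be ", n, " x 2")
  if (!all(is.finite(coords)))
    stop("coords contain non-finite values")
  if (!is.null(morphology)) {
    morphology <- as.matrix(morphology)
    if (nrow(morphology) != n)
      stop("morphology rows (", nrow(morphology), ") != expression rows (", n, ")")
  }
  if (!is.null(truth_labels) && length(truth_labels) != n)
    stop("truth_labels length != spot count")
  if (!normalized && prod(dim(expression)) > 0) {
    mn <- if (methods::is(expression, "sparseMatrix")) min(expression@x, 0) else min(expression)
    if (is.finite(mn) && mn < 0)
      stop("raw counts must be non-negative; got minimum ", mn)
  }
  rownames(coords) <- spot_ids
  structure(list(
    expression   = expression,
    coords       = coords,
    morphology   = morphology,
    spot_ids     = as.character(spot_ids),
    gene_ids     = as.character(gene_ids),
    truth_labels = if (is.null(truth_labels)) NULL else as.integer(truth_labels),
    normalized   = isTRUE(normalized)
  ), class = "srt_dataset")
}

#' @export
print.srt_dataset <- function(x, ...) {
  cat("srt_dataset:", nrow(x$expression), "spots x", ncol(x$expression), "genes\n")
  cat("  morphology:", if (is.null(x$morphology)) "absent" else
    paste0(ncol(x$morphology), " features"), "\n")
  cat("  truth labels:", if (is.null(x$truth_labels)) "absent" else
    paste0(length(unique(x$truth_labels)), " domains"), "\n")
  cat("  normalized:", x$normalized, "\n")
  invisible(x)
}

#' @export
dim.srt_dataset <- function(x) dim(x$expression)

# dense copy of the expression matrix
expr_dense <- function(ds) {
  x <- ds$expression
  if (methods::is(x, "sparseMatrix")) x <- as.matrix(x)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

#' Write a dataset as plain CSV tables
#'
#' Writes `expression.csv` (spots x genes, spot ids in the first column),
#' `coords.csv`, and `morphology.csv`/`labels.tsv` when present.  The pair
#' round-trips through [load_tables()].
#'
#' @param ds an `srt_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_srt_tables <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ex <- expr_dense(ds)
  df <- data.frame(spot = ds$spot_ids, ex, check.names = FALSE)
  colnames(df) <- c("spot", ds$gene_ids)
  utils::write.csv(df, file.path(dir, "expression.csv"), row.names = FALSE, quote = FALSE)
  cdf <- data.frame(spot = ds$spot_ids, x = ds$coords[, 1], y = ds$coords[, 2])
  utils::write.csv(cdf, file.path(dir, "coords.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(ds$morphology)) {
    m <- as.matrix(ds$morphology)
    mdf <- data.frame(spot = ds$spot_ids, m, check.names = FALSE)
    colnames(mdf) <- c("spot", paste0("m", seq_len(ncol(m))))
    utils::write.csv(mdf, file.path(dir, "morphology.csv"), row.names = FALSE, quote = FALSE)
  }
  if (!is.null(ds$truth_labels)) {
    utils::write.table(data.frame(spot = ds$spot_ids, domain = ds$truth_labels),
                       file.path(dir, "labels.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Write a dataset in the 10x Space Ranger on-disk layout
#'
#' Emits `matrix.mtx` (genes x barcodes, Matrix Market), `barcodes.tsv`,
#' `features.tsv` and a v2-style `tissue_positions.csv`, so that
#' [load_visium()] round-trips the container.  Counts are written as stored;
#' callers normally write raw-count datasets.
#'
#' @param ds an `srt_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_visium <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ex <- ds$expression
  m <- Matrix::Matrix(t(as.matrix(ex)), sparse = TRUE)  # genes x barcodes
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(ds$spot_ids, file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(id = ds$gene_ids, name = ds$gene_ids, type = "Gene Expression"),
    file.path(dir, "features.tsv"),
    sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  pos <- data.frame(
    barcode = ds$spot_ids,
    in_tissue = 1L,
    array_row = seq_along(ds$spot_ids) - 1L,
    array_col = seq_along(ds$spot_ids) - 1L,
    pxl_row_in_fullres = ds$coords[, 2],
    pxl_col_in_fullres = ds$coords[, 1])
  utils::write.csv(pos, file.path(dir, "tissue_positions.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
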