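#' Spatial domain identification by K-means
#'
#' Clusters the fused latent features with `n_init` seeded K-means restarts,
#' keeping the best inertia.  Deterministic given `seed`.
#'
#' @param Z spots x d feature matrix (a `latent_features` object is accepted).
#' @param k number of domains, `1 <= k <= n`.
#' @param seed RNG seed (default 0).
#' @param n_init number of restarts (default 10).
#' @return A `domain_labels` object: integer `labels` in `[0, k)`, `k`, `seed`.
#' @export
identify_domains <- function(Z, k, seed = 0, n_init = 10) {
  if (is.list(Z) && !is.null(Z$Z)) Z <- Z$Z
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]")
  labels <- if (k == 1) rep(0L, n) else with_seed(seed, {
    km <- stats::kmeans(Z, centers = k, nstart = n_init, iter.max = 100)
    as.integer(km$cluster) - 1L
  })
  structure(list(labels = labels, k = as.integer(k), seed = as.integer(seed)),
            class = "domain_labels")
}

label_vec <- function(x) {
  if (inherits(x, "domain_labels")) x$labels else x
}

#' Mean squared denoising error
#'
#' Mean over spots of the squared Euclidean row difference,
#' `(1/n) * sum_i ||x_i - x_hat_i||^2`; zero means perfect recovery.
#'
#' @param clean,denoised equal-shaped spots x genes matrices.
#' @return Non-negative scalar.
#' @export
evaluate_mse <- function(clean, denoised) {
  clean <- as.matrix(clean); denoised <- as.matrix(denoised)
  if (!all(dim(clean) == dim(denoised)))
    stop("shape mismatch: ", paste(dim(clean), collapse = "x"), " vs ",
         paste(dim(denoised), collapse = "x"))
  mean(rowSums((clean - denoised)^2))
}

#' Adjusted Rand Index
#'
#' Chance-corrected agreement between two partitions via the contingency
#' table; 1 for identical partitions (up to label names), ~0 for random
#' agreement, negative for worse-than-chance.
#'
#' @param a,b label vectors of equal length (any label alphabet).
#' @return Scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  a <- label_vec(a); b <- label_vec(b)
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  nC2 <- ch2(length(a))
  expected <- sum_a * sum_b / nC2
  denom <- (sum_a + sum_b) / 2 - expected
  # degenerate cases (both all-singletons or both one cluster): identical
  # pair structure scores 1, per the usual convention
  if (denom == 0) return(as.numeric(sum_a == sum_b && sum_ij == sum_a))
  (sum_ij - expected) / denom
}

davies_bouldin_index <- function(features, labels) {
  labs <- sort(unique(labels))
  k <- length(labs)
  cent <- do.call(rbind, lapply(labs, function(l)
    colMeans(features[labels == l, , drop = FALSE])))
  S <- vapply(seq_len(k), function(i) {
    pts <- features[labels == labs[i], , drop = FALSE]
    mean(sqrt(rowSums((pts - matrix(cent[i, ], nrow(pts), ncol(pts),
                                    byrow = TRUE))^2)))
  }, numeric(1))
  M <- as.matrix(stats::dist(cent))
  R <- outer(S, S, "+") / M
  diag(R) <- -Inf
  mean(apply(R, 1, max))
}

#' Clustering evaluation report
#'
#' Computes whichever metrics the provided inputs permit: ARI against
#' `truth`, and silhouette coefficient (SC, Euclidean; higher better) and
#' Davies-Bouldin index (DBI; lower better) from `features`.  Metrics that
#' cannot be computed (e.g. SC with a single cluster) are absent from the
#' report, never `NaN`.
#'
#' @param labels `domain_labels` or an integer vector.
#' @param truth optional ground-truth labels (enables ARI).
#' @param features optional spots x d matrix (enables SC and DBI).
#' @return An `evaluation_report` list with any of `ari`, `silhouette`,
#'   `davies_bouldin`.
#' @export
evaluate_clustering <- function(labels, truth = NULL, features = NULL) {
  lv <- label_vec(labels)
  rep <- list()
  if (!is.null(truth)) rep$ari <- adjusted_rand_index(lv, label_vec(truth))
  if (!is.null(features)) {
    features <- as.matrix(features)
    if (nrow(features) != length(lv))
      stop("features rows != label length")
    if (length(unique(lv)) < 2) {
      warning("silhouette/DBI undefined for a single cluster; omitted")
    } else {
      sil <- cluster::silhouette(as.integer(factor(lv)), stats::dist(features))
      rep$silhouette <- mean(sil[, "sil_width"])
      rep$davies_bouldin <- davies_bouldin_index(features, lv)
    }
  }
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  if (length(x) == 0) { cat("evaluation_report: (no metrics)\n"); return(invisible(x)) }
  cat("evaluation_report:\n")
  for (nm in names(x)) cat("  ", nm, ": ", format(x[[nm]], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact by exhaustive enumeration of group assignments (ties handled with
#' average ranks) whenever `choose(n, n1) <= 2e5`; exact via the null
#' rank-sum distribution when there are no ties and both groups have at most
#' 25 observations; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param x,y numeric samples for the two groups.
#' @return p-value in `[0, 1]`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (nx == 0 || ny == 0) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (choose(n, nx) <= 2e5) {
    combs <- utils::combn(n, nx)
    stats_all <- colSums(matrix(r[combs], nrow = nx))
    obs <- abs(W - mu)
    return(mean(abs(stats_all - mu) >= obs - 1e-9))
  }
  if (!ties && nx <= 25 && ny <= 25) {
    U <- W - nx * (nx + 1) / 2
    muU <- nx * ny / 2
    p <- if (U > muU) 2 * stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE)
    else 2 * stats::pwilcox(U, nx, ny)
    return(min(1, p))
  }
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma <- sqrt(nx * ny / 12 * ((n + 1) - tie_corr))
  if (sigma == 0) return(1)
  z <- W - mu
  z <- (z - sign(z) * 0.5) / sigma
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' One-vs-rest differential expression per spatial domain
#'
#' For each domain, tests every gene with a two-sided Wilcoxon rank-sum test
#' of in-domain vs all other spots, adjusts p-values per domain with
#' Benjamini-Hochberg, and reports genes passing all three filters:
#' detected (nonzero) in more than `pct_min` of the domain's spots,
#' `|log2FC| >= lfc_min`, and FDR `<= fdr_max`.  The fold change is computed
#' on de-logged means: `log2((mean(expm1(in)) + eps) / (mean(expm1(out)) +
#' eps))` with `eps = 1e-9`.
#'
#' @param ds normalized `srt_dataset` (or any spots x genes matrix via
#'   `expression=`); the matrix may equally be denoised output.
#' @param labels `domain_labels` or integer vector.
#' @param pct_min minimum detection fraction within the domain (default 0.8).
#' @param lfc_min minimum absolute log2 fold change (default 2).
#' @param fdr_max maximum BH-adjusted p (default 0.05).
#' @return data.frame of `deg_record`s: gene, domain, log2fc, pct_in, p, fdr.
#' @export
differential_expression <- function(ds, labels, pct_min = 0.8, lfc_min = 2,
                                    fdr_max = 0.05) {
  if (inherits(ds, "srt_dataset")) {
    if (!ds$normalized) stop("differential_expression expects normalized data")
    X <- expr_dense(ds)
    genes <- ds$gene_ids
  } else {
    X <- as.matrix(ds)
    genes <- colnames(X) %||% paste0("g", seq_len(ncol(X)))
  }
  lv <- label_vec(labels)
  if (length(lv) != nrow(X)) stop("labels length != spot count")
  doms <- sort(unique(lv))
  small <- doms[vapply(doms, function(d) sum(lv == d) < 2, logical(1))]
  if (length(small))
    stop("domain(s) with fewer than 2 spots: ", paste(small, collapse = ", "))
  eps <- 1e-9
  out <- list()
  for (d in doms) {
    inm <- lv == d
    Xin <- X[inm, , drop = FALSE]
    Xout <- X[!inm, , drop = FALSE]
    pct_in <- colMeans(Xin != 0)
    # de-logged means floored at 0: a no-op for log1p counts, and keeps the
    # ratio defined when the matrix holds continuous (possibly negative) data
    lfc <- log2((colMeans(pmax(expm1(Xin), 0)) + eps) /
                  (colMeans(pmax(expm1(Xout), 0)) + eps))
    p <- vapply(seq_len(ncol(X)),
                function(j) wilcoxon_rank_sum(Xin[, j], Xout[, j]),
                numeric(1))
    fdr <- stats::p.adjust(p, method = "BH")
    keep <- pct_in > pct_min & abs(lfc) >= lfc_min & fdr <= fdr_max
    if (any(keep)) {
      out[[length(out) + 1]] <- data.frame(
        gene = genes[keep], domain = d, log2fc = lfc[keep],
        pct_in = pct_in[keep], p = p[keep], fdr = fdr[keep],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene = character(), domain = integer(), log2fc = numeric(),
               pct_in = numeric(), p = numeric(), fdr = numeric())
  rownames(res) <- NULL
  res
}

#' Write DEG records as TSV
#' @param deg data.frame from [differential_expression()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_deg_tsv <- function(deg, path) {
  utils::write.table(deg, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write domain labels as a two-column TSV
#' @param labels `domain_labels` or integer vector.
#' @param spot_ids spot identifiers.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_labels_tsv <- function(labels, spot_ids, path) {
  utils::write.table(data.frame(spot = spot_ids, domain = label_vec(labels)),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an evaluation report as JSON
#' @param report `evaluation_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
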