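# fixtures are built in code; nothing is read from disk except what the
# package's own writers emit into tempdirs

# small raw-count dataset with fixed values
toy_counts_dataset <- function() {
  counts <- matrix(c(5, 0, 2, 1,
                     0, 3, 1, 0,
                     2, 2, 0, 4), nrow = 3, byrow = TRUE)
  srt_dataset(expression = counts,
              coords = cbind(c(0, 1, 0), c(0, 0, 1)),
              spot_ids = c("AAA-1", "BBB-1", "CCC-1"),
              gene_ids = c("g1", "g2", "g3", "g4"))
}

# random raw-count dataset
random_counts_dataset <- function(n = 20, g = 15, seed = 1) {
  set.seed(seed)
  counts <- matrix(rpois(n * g, lambda = 2), n, g)
  srt_dataset(expression = counts,
              coords = matrix(runif(2 * n, 0, 10), n, 2),
              spot_ids = sprintf("s%02d", seq_len(n)),
              gene_ids = sprintf("g%02d", seq_len(g)))
}

# random symmetric binary graph as an affinity_graph-compatible input
random_binary_graph <- function(n, p = 0.2, seed = 1) {
  set.seed(seed)
  A <- matrix(rbinom(n * n, 1, p), n, n)
  A <- 1 * ((A + t(A)) > 0)
  diag(A) <- 0
  A
}

# dense brute-force oracle for the low-pass filter: explicit matrix power
dense_filter_oracle <- function(Y, A, t) {
  n <- nrow(A)
  At <- A + diag(n)
  d <- rowSums(At)
  H <- diag(1 / sqrt(d)) %*% At %*% diag(1 / sqrt(d))
  Ht <- diag(n)
  for (i in seq_len(t)) Ht <- Ht %*% H
  Ht %*% Y
}

# independent exhaustive permutation oracle for the two-sided rank-sum test:
# statistic is the Mann-Whitney U computed by pair counting (not rank sums)
wilcoxon_perm_oracle <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  vals <- c(x, y)
  ustat <- function(idx) {
    a <- vals[idx]; b <- vals[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  obs <- abs(ustat(seq_len(nx)) - nx * (n - nx) / 2)
  combs <- utils::combn(n, nx)
  stats <- apply(combs, 2, ustat)
  mean(abs(stats - nx * (n - nx) / 2) >= obs - 1e-9)
}

# pair-counting oracle for the adjusted Rand index
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  ss <- sd_ <- ds <- dd <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) ss <- ss + 1
    else if (sa && !sb) sd_ <- sd_ + 1
    else if (!sa && sb) ds <- ds + 1
    else dd <- dd + 1
  }
  num <- 2 * (ss * dd - sd_ * ds)
  den <- (ss + sd_) * (sd_ + dd) + (ss + ds) * (ds + dd)
  if (den == 0) return(1)
  num / den
}
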