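# Shared fixtures: all built in code, nothing read from disk.

# small positive SUVR-like matrix with reproducible noise
make_values <- function(n, d, seed = 1, base = 1.2, sd = 0.1) {
  set.seed(seed)
  matrix(stats::rnorm(n * d, base, sd), n, d)
}

make_dataset <- function(n = 30, d = 6, seed = 1, group = "CU", ...) {
  suvr_dataset(make_values(n, d, seed), group = group, ...)
}

# quick 3-group synthetic cohort at reduced scale
small_cohort <- function(n_per_group = 60, d = 16, seed = 42,
                         rho_in = 0.6, rho_out = 0.2) {
  spec <- cohort_spec(
    n_subjects = stats::setNames(rep(n_per_group, 3L), c("CU", "MCI", "AD")),
    d = d, n_blocks = 4L, rho_in = rho_in, rho_out = rho_out)
  generate_cohort(spec, seed = seed)
}

# build an mbn_network directly from a weight matrix (p-values optional)
toy_network <- function(w, pvalues = NULL) {
  w <- as.matrix(w)
  diag(w) <- 0
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  mbn_network(w, pvalues = pvalues)
}

# ---- independent oracles -------------------------------------------------

# Pearson r by direct evaluation of the sum formula
oracle_pearson <- function(p, q) {
  mp <- sum(p) / length(p)
  mq <- sum(q) / length(q)
  sum((p - mp) * (q - mq)) /
    (sqrt(sum((p - mp)^2)) * sqrt(sum((q - mq)^2)))
}

# Benjamini-Hochberg step-up by brute force: returns logical reject vector
oracle_bh <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= (seq_len(m) / m) * alpha)
  reject <- logical(m)
  if (length(below) > 0L) reject[ord[seq_len(max(below))]] <- TRUE
  reject
}

# directed/undirected Hausdorff by exhaustive scan over all row pairs
oracle_hausdorff <- function(A, B) {
  d <- nrow(A)
  D <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(d))
    D[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
  h_ab <- max(apply(D, 1L, min))
  h_ba <- max(apply(D, 2L, min))
  max(h_ab, h_ba)
}

# graph features by brute force: Floyd-Warshall efficiency, direct triangle
# count for clustering, endpoint-degree Pearson correlation for assortativity
oracle_graph_features <- function(w) {
  d <- nrow(w)
  A <- (w != 0) * 1
  diag(A) <- 0
  deg <- rowSums(A)
  dens <- sum(A) / (d * (d - 1))
  ad <- mean(deg)
  as_ <- mean(rowSums(abs(w)))
  # Floyd-Warshall on lengths 1/|w|
  len <- ifelse(A == 1, 1 / abs(w), Inf)
  diag(len) <- 0
  for (k in seq_len(d)) for (i in seq_len(d)) for (j in seq_len(d))
    if (len[i, k] + len[k, j] < len[i, j]) len[i, j] <- len[i, k] + len[k, j]
  inv <- 1 / len
  diag(inv) <- 0
  ge <- sum(inv[is.finite(inv)]) / (d * (d - 1))
  # local clustering: triangles among neighbours
  cc <- vapply(seq_len(d), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2L) return(0)
    links <- sum(A[nb, nb]) / 2
    links / (k * (k - 1) / 2)
  }, numeric(1L))
  acc <- mean(cc)
  # assortativity: correlation of endpoint degrees over directed edge list
  ei <- which(A == 1, arr.ind = TRUE)
  ac <- if (nrow(ei) == 0L || stats::sd(deg[ei[, 1L]]) == 0) 0
        else stats::cor(deg[ei[, 1L]], deg[ei[, 2L]])
  c(ge = ge, ac = ac, ad = ad, as = as_, d = dens, acc = acc)
}
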