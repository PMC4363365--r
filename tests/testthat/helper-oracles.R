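# Independent oracles and small constructors used across the suite.

# Phi coefficient from the 2x2 contingency table of two binary vectors:
# (n11 n00 - n10 n01) / sqrt(n1. n0. n.1 n.0)
phi_oracle <- function(x, y) {
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
  den <- sqrt((n11 + n10) * (n01 + n00)) * sqrt((n11 + n01) * (n10 + n00))
  if (den == 0) return(NA_real_)
  (n11 * n00 - n10 * n01) / den
}

# Build two binary vectors realizing given 2x2 cell counts.
vectors_from_table <- function(n11, n10, n01, n00) {
  list(x = rep(c(1, 1, 0, 0), c(n11, n10, n01, n00)),
       y = rep(c(1, 0, 1, 0), c(n11, n10, n01, n00)))
}

# All-pairs shortest paths by Floyd-Warshall; returns max finite
# off-diagonal distance (NA if no edges).
floyd_diameter <- function(adj) {
  k <- nrow(adj)
  d <- matrix(Inf, k, k)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (m in seq_len(k)) for (i in seq_len(k)) for (j in seq_len(k))
    if (d[i, m] + d[m, j] < d[i, j]) d[i, j] <- d[i, m] + d[m, j]
  off <- d[upper.tri(d)]
  if (!any(is.finite(off))) return(NA_real_)
  max(off[is.finite(off)])
}

# Unordered edge set of a 0/1 adjacency matrix as "i-j" strings (i < j).
edge_set <- function(adj, ids = seq_len(nrow(adj))) {
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  paste(ids[idx[, 1]], ids[idx[, 2]], sep = "-")
}

# Wrap a plain symmetric 0/1 matrix as a band_adj object.
make_adj <- function(b, ids = seq_len(nrow(b)), group = "X", n = 50,
                     alpha = 0.05) {
  b <- matrix(as.integer(b), nrow = nrow(b))
  dimnames(b) <- list(ids, ids)
  structure(list(b = b, alpha = alpha, correction = "none",
                 band_ids = as.integer(ids), n = n, group = group,
                 n_zero_variance = 0L),
            class = "band_adj")
}

# Wrap a coefficient matrix as a band_cor object.
make_cor <- function(r, ids = seq_len(nrow(r)), n = 50, group = "X") {
  dimnames(r) <- list(ids, ids)
  structure(list(r = r, n = n, band_ids = as.integer(ids),
                 undefined = rep(FALSE, nrow(r)), group = group),
            class = "band_cor")
}

# Symmetric 0/1 adjacency of an Erdos-Renyi graph.
random_adj <- function(k, p = 0.2) {
  b <- matrix(0L, k, k)
  b[upper.tri(b)] <- stats::rbinom(k * (k - 1) / 2, 1, p)
  b + t(b)
}

# Random binary band matrix.
random_bm <- function(n, k, prev = 0.5, group = "X") {
  band_matrix(matrix(stats::rbinom(n * k, 1, prev), nrow = n),
              group = group)
}

# Build a band_adj from an edge list of unordered pairs over given ids.
adj_from_pairs <- function(pairs, ids, group = "X") {
  k <- length(ids)
  b <- matrix(0L, k, k)
  pos <- match(c(pairs[, 1], pairs[, 2]), ids)
  i <- pos[seq_len(nrow(pairs))]
  j <- pos[nrow(pairs) + seq_len(nrow(pairs))]
  b[cbind(i, j)] <- 1L
  b[cbind(j, i)] <- 1L
  make_adj(b, ids = ids, group = group)
}

# Rows of the table 4 fixture whose printed count differs from the printed
# list length (typographical defects in the source table, transcribed
# faithfully).
table4_known_defects <- data.frame(
  comparison = c("H_vs_BC", "H_vs_BBP", "BBP_vs_BC"),
  node = c(12L, 102L, 6L))
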