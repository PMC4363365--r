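# Connection-intensity statistics.
#
# For each node: N = number of significant correlations involving it (its
# degree in B), M = signed mean of the Pearson coefficients over those N
# pairs, I = N * M. At the group level N_k is the count of ones in B,
# M_k the signed mean of r over all significant entries, I_k = M_k * N_k.
# M averages over significant pairs only -- the reference table contains
# negative M and near-zero M with large N, which rules out averaging
# magnitudes or averaging over all pairs.

#' Per-node connection intensity table
#'
#' One record per band: degree `N`, signed mean correlation `M` over the
#' node's significant pairs (0 when isolated), intensity `I = N * M`, and
#' `rank` by descending `I` (ties broken by ascending band id).
#'
#' @param c a `band_cor` from [correlation_matrix()].
#' @param b the matching `band_adj` from [binarize()].
#' @return data.frame with columns `node`, `N`, `M`, `I`, `rank`.
#' @examples
#' m <- generate_cohort(synthetic_config(50, 12, rho_within = 0.5, seed = 4))
#' c <- correlation_matrix(m)
#' head(node_intensity_table(c, binarize(c)))
#' @export
node_intensity_table <- function(c, b) {
  stopifnot(inherits(c, "band_cor"), inherits(b, "band_adj"))
  if (!identical(c$band_ids, b$band_ids))
    stop("correlation and adjacency matrices have different band ids",
         call. = FALSE)
  k <- length(b$band_ids)
  N <- rowSums(b$b)
  M <- vapply(seq_len(k), function(i) {
    sel <- b$b[i, ] == 1L
    if (!any(sel)) 0 else mean(c$r[i, sel])
  }, numeric(1))
  I <- N * M
  out <- data.frame(node = b$band_ids, N = as.integer(N), M = M, I = I)
  ord <- order(-out$I, out$node)
  out$rank <- integer(k)
  out$rank[ord] <- seq_len(k)
  out
}

#' Group-level connection intensity
#'
#' @param c a `band_cor`.
#' @param b the matching `band_adj`.
#' @return List of class `group_intensity`: `group`, `N_k` (ones in B),
#'   `M_k` (signed mean r over significant entries; 0 when no links),
#'   `I_k = M_k * N_k`, `sum_I` (sum of per-node I) and
#'   `mean_I = sum_I / n_nodes`.
#' @export
group_intensity <- function(c, b) {
  tab <- node_intensity_table(c, b)
  N_k <- sum(b$b)
  M_k <- if (N_k == 0) 0 else mean(c$r[b$b == 1L])
  structure(list(group = b$group, N_k = N_k, M_k = M_k,
                 I_k = M_k * N_k, sum_I = sum(tab$I),
                 mean_I = sum(tab$I) / nrow(tab)),
            class = "group_intensity")
}

#' @export
print.group_intensity <- function(x, ...) {
  cat("group_intensity (", x$group, "): N_k = ", x$N_k,
      ", M_k = ", sprintf("%.4f", x$M_k),
      ", I_k = ", sprintf("%.2f", x$I_k),
      ", mean per-node I = ", sprintf("%.4f", x$mean_I), "\n", sep = "")
  invisible(x)
}
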