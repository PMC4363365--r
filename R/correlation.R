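# Pearson correlation networks over binary band profiles.
#
# For 0/1 data the Pearson coefficient is the phi coefficient of the 2x2
# contingency table; significance follows the t rule
#   t = r sqrt(n - 2) / sqrt(1 - r^2),  df = n - 2,
# with a link declared when the two-tailed p-value falls below alpha
# (equivalently, one-tailed p < alpha/2).

#' Pearson (phi) correlation of two binary vectors
#'
#' @param x,y equal-length vectors of 0/1 values, length >= 3.
#' @return The Pearson coefficient, or `NA_real_` when either vector has
#'   zero variance (constant band), in which case the correlation is
#'   undefined.
#' @examples
#' pearson_binary(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
pearson_binary <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' All pairwise band correlations for a cohort
#'
#' @param m a [band_matrix] with at least 3 participants and 2 bands.
#' @return An object of class `band_cor`: list with `r` (symmetric matrix
#'   of coefficients, `NA` where a band has zero variance, unit diagonal
#'   where defined), `n` (sample size), `band_ids`, `undefined` (logical:
#'   zero-variance bands) and `group`.
#' @export
correlation_matrix <- function(m) {
  stopifnot(inherits(m, "band_matrix"))
  if (m$n < 3) stop("need at least 3 participants", call. = FALSE)
  if (length(m$band_ids) < 2) stop("need at least 2 bands", call. = FALSE)
  v <- m$values
  undefined <- apply(v, 2, function(col) stats::var(col) == 0)
  r <- suppressWarnings(stats::cor(v))
  r[undefined, ] <- NA_real_
  r[, undefined] <- NA_real_
  diag(r)[!undefined] <- 1
  dimnames(r) <- list(m$band_ids, m$band_ids)
  structure(list(r = r, n = m$n, band_ids = m$band_ids,
                 undefined = unname(undefined), group = m$group),
            class = "band_cor")
}

#' The t statistic for testing a Pearson correlation against zero
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2` degrees of freedom;
#' `|r| = 1` maps to a signed infinity (and a p-value of zero downstream).
#'
#' @param r coefficient(s) in `[-1, 1]` (NA propagates).
#' @param n sample size, >= 3.
#' @return t statistic(s), same shape as `r`.
#' @examples
#' t_statistic(0.6, 50)  # 5.196
#' @export
t_statistic <- function(r, n) {
  if (n < 3) stop("n must be at least 3", call. = FALSE)
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("|r| must not exceed 1", call. = FALSE)
  t <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  t[!is.na(r) & abs(r) >= 1] <- sign(r[!is.na(r) & abs(r) >= 1]) * Inf
  t
}

#' Significance of all pairwise correlations
#'
#' @param c a `band_cor` from [correlation_matrix()].
#' @return List of class `band_sig` with `t`, two-tailed `p`, and `df`
#'   (`n - 2`). Diagonal and undefined pairs are `NA`.
#' @export
cor_significance <- function(c) {
  stopifnot(inherits(c, "band_cor"))
  t <- t_statistic(c$r, c$n)
  p <- 2 * stats::pt(abs(t), df = c$n - 2, lower.tail = FALSE)
  diag(t) <- NA_real_
  diag(p) <- NA_real_
  structure(list(t = t, p = p, df = c$n - 2L), class = "band_sig")
}

#' Binarize a correlation matrix into a link adjacency matrix
#'
#' A link `b_ij = 1` is declared exactly when the pair's two-tailed
#' p-value under the t reference distribution falls below `alpha`
#' (equivalently, one-tailed p below `alpha/2`) and both bands have
#' nonzero variance. Perfect correlations (`|r| = 1`) have p = 0 and are
#' always significant. Each of the `choose(k, 2)` pairs is tested at the
#' raw level by default, matching the original analysis; set `correction`
#' to adjust for multiplicity instead.
#'
#' @param c a `band_cor` from [correlation_matrix()].
#' @param alpha two-tailed significance level in (0, 1).
#' @param correction `"none"` (default), `"bonferroni"` or `"BH"`; applied
#'   to the vector of unique-pair p-values via [stats::p.adjust()].
#' @return Object of class `band_adj`: list with `b` (symmetric 0/1
#'   integer matrix, zero diagonal), `alpha`, `correction`, `band_ids`,
#'   `n`, `group` and `n_zero_variance` (count of undefined bands, which
#'   receive no links).
#' @examples
#' m <- generate_cohort(synthetic_config(50, 10, rho_within = 0.6, seed = 2))
#' a <- binarize(correlation_matrix(m), alpha = 0.05)
#' link_count(a)
#' @export
binarize <- function(c, alpha = 0.05, correction = c("none", "bonferroni",
                                                     "BH")) {
  stopifnot(inherits(c, "band_cor"))
  correction <- match.arg(correction)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single number in (0, 1)", call. = FALSE)
  p <- cor_significance(c)$p
  if (correction != "none") {
    ut <- upper.tri(p)
    p[ut] <- stats::p.adjust(p[ut], method = correction)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  b <- (p < alpha) + 0L
  b[is.na(b)] <- 0L
  diag(b) <- 0L
  dimnames(b) <- list(c$band_ids, c$band_ids)
  structure(list(b = b, alpha = alpha, correction = correction,
                 band_ids = c$band_ids, n = c$n, group = c$group,
                 n_zero_variance = sum(c$undefined)),
            class = "band_adj")
}

#' The |r| significance boundary of the t rule
#'
#' Inverts the t formula at the critical two-tailed t value: pairs with
#' `|r|` above the returned boundary are declared significant at `alpha`.
#' At `n = 50`, `alpha = 0.05` the boundary is about 0.2787.
#'
#' @param n sample size.
#' @param alpha two-tailed level.
#' @return The critical |r|.
#' @export
critical_r <- function(n, alpha = 0.05) {
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(tc^2 + (n - 2))
}

#' Convert an adjacency matrix to an igraph graph
#'
#' @param b a `band_adj` from [binarize()].
#' @param c optional `band_cor`; if supplied, coefficients are attached as
#'   the `r` edge attribute (used as weight in GraphML export).
#' @return An undirected [igraph::graph].
#' @export
as_band_graph <- function(b, c = NULL) {
  stopifnot(inherits(b, "band_adj"))
  g <- igraph::graph_from_adjacency_matrix(b$b, mode = "undirected")
  if (!is.null(c)) {
    el <- igraph::as_edgelist(g, names = TRUE)
    igraph::E(g)$r <- c$r[cbind(el[, 1], el[, 2])]
    igraph::E(g)$weight <- igraph::E(g)$r
  }
  g
}

#' Export the significant-link edge list
#'
#' Writes one row per unique link: `node_a`, `node_b`, `r`, `p`.
#'
#' @param c a `band_cor`.
#' @param b the matching `band_adj`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(c, b, path) {
  stopifnot(inherits(c, "band_cor"), inherits(b, "band_adj"))
  sig <- cor_significance(c)
  idx <- which(upper.tri(b$b) & b$b == 1L, arr.ind = TRUE)
  df <- data.frame(node_a = b$band_ids[idx[, 1]],
                   node_b = b$band_ids[idx[, 2]],
                   r = c$r[idx], p = sig$p[idx])
  df <- df[order(df$node_a, df$node_b), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
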