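# Network attributes of a link adjacency matrix.
#
# Link counting follows the source convention: the number of links is the
# number of ones in the symmetric matrix B, i.e. each unordered edge is
# counted twice and the link count equals the sum of node degrees.

#' Number of links (ones in B)
#'
#' @param b a `band_adj` from [binarize()].
#' @return Integer count of off-diagonal ones (twice the unique edges).
#' @export
link_count <- function(b) {
  stopifnot(inherits(b, "band_adj"))
  sum(b$b)
}

#' Per-node sociometric degrees
#'
#' @param b a `band_adj`.
#' @return Named integer vector of row sums of B (names = band ids).
#' @export
degrees <- function(b) {
  stopifnot(inherits(b, "band_adj"))
  d <- rowSums(b$b)
  names(d) <- b$band_ids
  d
}

#' Network density
#'
#' Two conventions are reported. `"links"` (default) divides the unique
#' edge count by `n(n-1)`, the number of ordered node pairs -- the
#' convention that reproduces the published per-group values (a complete
#' graph scores 0.5). `"undirected"` is the standard undirected density,
#' unique edges over `n(n-1)/2` (complete graph scores 1).
#'
#' @param b a `band_adj` with at least 2 nodes.
#' @param convention `"links"` or `"undirected"`.
#' @return Density in `[0, 0.5]` or `[0, 1]` respectively.
#' @export
net_density <- function(b, convention = c("links", "undirected")) {
  stopifnot(inherits(b, "band_adj"))
  convention <- match.arg(convention)
  k <- length(b$band_ids)
  if (k < 2) stop("need at least 2 nodes", call. = FALSE)
  edges <- sum(b$b) / 2
  switch(convention,
         links = edges / (k * (k - 1)),
         undirected = edges / (k * (k - 1) / 2))
}

#' Network diameter over connected pairs
#'
#' The maximum shortest-path length (in links) over all pairs of nodes
#' that are connected; disconnected pairs are excluded, so the diameter of
#' a disconnected graph is the largest within-component eccentricity. The
#' component count is attached as an attribute.
#'
#' @param b a `band_adj` with at least one edge; an edgeless graph yields
#'   `NA` with a warning (undefined diameter).
#' @return Integer diameter, with attribute `n_components`.
#' @export
net_diameter <- function(b) {
  stopifnot(inherits(b, "band_adj"))
  g <- as_band_graph(b)
  comp <- igraph::components(g)$no
  if (igraph::ecount(g) == 0) {
    warning("edgeless graph: diameter undefined")
    return(structure(NA_real_, n_components = comp))
  }
  d <- igraph::distances(g)
  structure(max(d[is.finite(d)]), n_components = comp)
}

#' Summary of network attributes
#'
#' Computes the per-group attribute set of the reference analysis: node
#' and link counts, density (both conventions), diameter, the most
#' connected node (hub; ties broken by smallest band id), and degree
#' statistics.
#'
#' @param b a `band_adj`.
#' @return Object of class `network_summary` (also a list): `n_nodes`,
#'   `n_links`, `density`, `density_undirected`, `diameter`,
#'   `n_components`, `top_node`, `degree_min`, `degree_max`,
#'   `degree_mean` (= n_links / n_nodes), `degree_sd`, `degree_var`.
#' @export
network_summary <- function(b) {
  stopifnot(inherits(b, "band_adj"))
  d <- degrees(b)
  dia <- if (sum(b$b) > 0) net_diameter(b)
         else suppressWarnings(net_diameter(b))
  structure(list(
    group = b$group,
    n_nodes = length(d),
    n_links = sum(d),
    density = net_density(b, "links"),
    density_undirected = net_density(b, "undirected"),
    diameter = as.numeric(dia),
    n_components = attr(dia, "n_components"),
    top_node = b$band_ids[which.max(d)],
    degree_min = min(d),
    degree_max = max(d),
    degree_mean = sum(d) / length(d),
    degree_sd = stats::sd(d),
    degree_var = stats::var(d)),
    class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("network_summary (group ", x$group, "): ", x$n_nodes, " nodes, ",
      x$n_links, " links, density ", sprintf("%.4f", x$density),
      ", diameter ", x$diameter, ", top node ", x$top_node,
      " (", x$degree_max, " links)\n", sep = "")
  invisible(x)
}

#' Degree-class histogram
#'
#' Shares (%) of nodes falling in the five published degree classes:
#' 2--6, 7--12, 13--18, 19--24 and 25+ links. Nodes with fewer than 2
#' links fall outside the classes and are reported as the `remainder`
#' attribute. Nodes with strictly more than `hub_threshold` links are
#' counted as hubs.
#'
#' @param d per-node degree vector (from [degrees()]).
#' @param hub_threshold hub cutoff; a node is a hub when its degree
#'   exceeds this value (default 19).
#' @return data.frame with `class` and `freq_percent`, plus attributes
#'   `remainder_percent` and `hub_percent`.
#' @export
degree_histogram <- function(d, hub_threshold = 19) {
  labels <- c("2-6", "7-12", "13-18", "19-24", "25+")
  counts <- c(sum(d >= 2 & d <= 6), sum(d >= 7 & d <= 12),
              sum(d >= 13 & d <= 18), sum(d >= 19 & d <= 24),
              sum(d >= 25))
  n <- length(d)
  out <- data.frame(class = labels,
                    freq_percent = if (n) 100 * counts / n else 0 * counts)
  attr(out, "remainder_percent") <- if (n) 100 * sum(d < 2) / n else 0
  attr(out, "hub_percent") <- if (n) 100 * sum(d > hub_threshold) / n else 0
  attr(out, "hub_threshold") <- hub_threshold
  out
}
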