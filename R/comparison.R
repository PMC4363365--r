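#' Kruskal-Wallis rank test across groups
#'
#' Rank-based H statistic with tie correction and the chi-square
#' approximation on `g - 1` degrees of freedom, computed from the rank
#' formula:
#' \deqn{H = \frac{12}{N(N+1)} \sum_k R_k^2 / n_k - 3(N+1)}
#' divided by the tie-correction factor
#' \eqn{1 - \sum_t (t^3 - t)/(N^3 - N)}. Used to compare per-node degree
#' or intensity vectors across the group networks. When every value in
#' every group is identical, the statistic is degenerate and reported as
#' 0 with p = 1.
#'
#' @param samples list of numeric vectors, one per group (>= 2 nonempty
#'   groups).
#' @return List of class `kruskal_wallis`: `statistic` (H), `df`, `p`
#'   (upper-tail chi-square probability), `n` (total observations) and
#'   `groups` (labels, from `names(samples)` if present).
#' @examples
#' kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9)))
#' @export
kruskal_wallis <- function(samples) {
  if (!is.list(samples) || length(samples) < 2)
    stop("need a list of at least two groups", call. = FALSE)
  if (any(!vapply(samples, length, 1L)))
    stop("every group must be nonempty", call. = FALSE)
  labels <- names(samples) %||% paste0("group", seq_along(samples))
  x <- unlist(samples, use.names = FALSE)
  if (anyNA(x)) stop("missing values are not allowed", call. = FALSE)
  g <- rep(seq_along(samples), lengths(samples))
  n <- length(x)
  df <- length(samples) - 1L
  if (length(unique(x)) == 1L) {
    return(structure(list(statistic = 0, df = df, p = 1, n = n,
                          groups = labels), class = "kruskal_wallis"))
  }
  rk <- rank(x)                      # midranks for ties
  rank_sums <- tapply(rk, g, sum)
  h <- 12 / (n * (n + 1)) * sum(rank_sums^2 / lengths(samples)) -
    3 * (n + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / correction
  structure(list(statistic = h, df = df,
                 p = stats::pchisq(h, df, lower.tail = FALSE),
                 n = n, groups = labels),
            class = "kruskal_wallis")
}

#' @export
print.kruskal_wallis <- function(x, ...) {
  cat("Kruskal-Wallis: H = ", sprintf("%.4f", x$statistic),
      ", df = ", x$df, ", p = ", format.pval(x$p, digits = 4),
      " (groups: ", paste(x$groups, collapse = ", "), ")\n", sep = "")
  invisible(x)
}
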