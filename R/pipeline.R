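# End-to-end orchestration: cohorts -> per-group networks -> attribute
# tables, intensity tables, disconnection ledgers, group comparisons.

#' Run the full band-network analysis
#'
#' For each group: pairwise correlations, t-rule binarization at `alpha`,
#' network summary, degree-class histogram and intensity table. For each
#' ordered pair of groups: a disconnection ledger. Across groups (when at
#' least two): Kruskal-Wallis comparisons of the per-node degree and
#' per-node intensity vectors. Optionally writes the full report bundle
#' (TSV tables, edge lists, GraphML graphs, JSON manifest) to
#' `output_dir`.
#'
#' @param groups either a named list of [band_matrix] objects / file
#'   paths (names = group labels), or a named list of
#'   [synthetic_config()] objects (e.g. from [default_scenario()]), in
#'   which case cohorts are generated first.
#' @param alpha two-tailed significance level for links (default 0.05).
#' @param hub_threshold hub cutoff passed to [degree_histogram()].
#' @param correction multiplicity handling passed to [binarize()]
#'   (default `"none"`, matching the reference analysis).
#' @param output_dir optional directory for the report bundle.
#' @return Object of class `abnet_report`: list with `groups` (per group:
#'   `matrix`, `cor`, `adj`, `summary`, `histogram`, `intensity`,
#'   `group_intensity`), `ledgers` (per ordered pair), `comparisons`
#'   (Kruskal-Wallis on degrees and intensities, `NULL` for a single
#'   group) and `manifest`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(default_scenario(seed = 1))
#' rep$groups$H$summary
#' }
#' @export
run_pipeline <- function(groups, alpha = 0.05, hub_threshold = 19,
                         correction = "none", output_dir = NULL) {
  if (!is.list(groups) || is.null(names(groups)) ||
      any(!nzchar(names(groups))))
    stop("groups must be a named list", call. = FALSE)
  mats <- lapply(names(groups), function(gname) {
    g <- groups[[gname]]
    if (inherits(g, "synthetic_config")) generate_cohort(g, group = gname)
    else if (inherits(g, "band_matrix")) { g$group <- gname; g }
    else if (is.character(g)) read_band_matrix(g, group = gname)
    else stop("pipeline stage 'input' (group ", gname,
              "): expected a band_matrix, a synthetic_config or a path",
              call. = FALSE)
  })
  names(mats) <- names(groups)

  per_group <- lapply(mats, function(m) {
    c <- correlation_matrix(m)
    b <- binarize(c, alpha = alpha, correction = correction)
    d <- degrees(b)
    list(matrix = m, cor = c, adj = b,
         summary = network_summary(b),
         histogram = degree_histogram(d, hub_threshold = hub_threshold),
         intensity = node_intensity_table(c, b),
         group_intensity = group_intensity(c, b))
  })

  gn <- names(per_group)
  ledgers <- list()
  if (length(gn) >= 2) {
    for (a in gn) for (bb in gn) if (a != bb) {
      ledgers[[paste0(a, "_vs_", bb)]] <-
        disconnection_ledger(per_group[[a]]$adj, per_group[[bb]]$adj)
    }
  }

  comparisons <- NULL
  if (length(gn) >= 2) {
    deg <- lapply(per_group, function(g) unname(degrees(g$adj)))
    ints <- lapply(per_group, function(g) g$intensity$I)
    comparisons <- list(degree = kruskal_wallis(deg),
                        intensity = kruskal_wallis(ints))
  } else {
    message("single group: between-group comparisons skipped")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("abnet")),
    alpha = alpha, hub_threshold = hub_threshold,
    correction = correction,
    groups = lapply(per_group, function(g) list(
      n_participants = g$matrix$n,
      n_bands = length(g$matrix$band_ids),
      n_links = link_count(g$adj),
      n_zero_variance_bands = g$adj$n_zero_variance)))

  report <- structure(list(groups = per_group, ledgers = ledgers,
                           comparisons = comparisons, manifest = manifest),
                      class = "abnet_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' Write an analysis report bundle to disk
#'
#' Per group: band matrix, network summary (TSV), degree histogram,
#' intensity table, edge list and GraphML graph. Per comparison: the
#' disconnection ledger. Plus `comparisons.json` and `manifest.json`.
#'
#' @param report an `abnet_report` from [run_pipeline()].
#' @param output_dir directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_report <- function(report, output_dir) {
  stopifnot(inherits(report, "abnet_report"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(output_dir, paste0(...))
  for (g in names(report$groups)) {
    x <- report$groups[[g]]
    write_band_matrix(x$matrix, fp(g, "_band_matrix.tsv"))
    s <- x$summary
    utils::write.table(
      data.frame(attribute = setdiff(names(s), "group"),
                 value = unlist(s[setdiff(names(s), "group")])),
      fp(g, "_summary.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(x$histogram, fp(g, "_degree_histogram.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(x$intensity, fp(g, "_intensity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_edge_list(x$cor, x$adj, fp(g, "_edges.tsv"))
    igraph::write_graph(as_band_graph(x$adj, x$cor),
                        fp(g, "_network.graphml"), format = "graphml")
  }
  for (cmp in names(report$ledgers)) {
    utils::write.table(report$ledgers[[cmp]], fp(cmp, "_ledger.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$comparisons)) {
    jsonlite::write_json(
      lapply(report$comparisons, function(k)
        k[c("statistic", "df", "p", "n", "groups")]),
      fp("comparisons.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(report$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}

#' Cross-check the packaged reference tables against each other
#'
#' Recomputes the table 2 cells that are derivable from the table 3
#' fixture -- per-group link counts (sum of the N column), maximum degree,
#' its node (argmax of N), minimum degree and mean degree -- and diffs
#' them against the table 2 fixture.
#'
#' @return data.frame with one row per (group, attribute): `expected`
#'   (table 2), `computed` (from table 3) and `match`.
#' @examples
#' chk <- fixtures_check()
#' all(chk$match[chk$attribute %in% c("n_links", "top_node")])
#' @export
fixtures_check <- function() {
  t2 <- load_fixture(2)
  t3 <- load_fixture(3)
  rows <- list()
  for (g in c("H", "BBP", "BC")) {
    tg <- t3[t3$group == g, ]
    expected <- function(attr) t2[[g]][t2$attribute == attr]
    add <- function(attr, computed, tol = 0) {
      rows[[length(rows) + 1]] <<- data.frame(
        group = g, attribute = attr, expected = expected(attr),
        computed = computed,
        match = abs(expected(attr) - computed) <= tol)
    }
    add("n_links", sum(tg$N))
    add("degree_max", max(tg$N))
    add("top_node", tg$node[which.max(tg$N)])
    add("degree_min", min(tg$N))
    # printed means are rounded to 2 decimals
    add("degree_mean", sum(tg$N) / nrow(tg), tol = 0.005)
  }
  do.call(rbind, rows)
}
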