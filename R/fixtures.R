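#' Load the packaged reference tables
#'
#' The package ships plain-text transcriptions of the published reference
#' tables for the three-cohort immunoblot study (H, BBP, BC; 121 bands):
#' * table 2 -- per-group network attributes (links, density, diameter,
#'   degree statistics, most-connected node);
#' * table 3 -- per-band N / M / I = N x M and intensity rank, per group
#'   (121 rows per group), plus a `totals` attribute with the printed
#'   column totals;
#' * table 4 -- disconnection ledgers for the three ordered comparisons
#'   (`H_vs_BC`, `H_vs_BBP`, `BBP_vs_BC`). Each lost link is printed once,
#'   under its lower-numbered node, so `lost_partners` ids always exceed
#'   `node`.
#'
#' The transcriptions are cell-for-cell faithful, including a handful of
#' typographical defects in the printed table 4 (rows whose printed count
#' differs from the printed list length, and garbled ids); see the package
#' vignette.
#'
#' @param table which table to load: 2, 3 or 4.
#' @return A data.frame. For table 3 the printed totals row is attached as
#'   `attr(x, "totals")`. For table 4, `lost_partners` is a comma-joined
#'   string of band ids (empty for nodes with no losses).
#' @examples
#' t2 <- load_fixture(2)
#' t2[t2$attribute == "n_links", ]
#' @export
load_fixture <- function(table = c(2, 3, 4)) {
  table <- as.integer(table[1])
  file <- switch(as.character(table),
    "2" = "table2_network_attributes.tsv",
    "3" = "table3_node_intensity.tsv",
    "4" = "table4_disconnections.tsv",
    stop("table must be 2, 3 or 4", call. = FALSE))
  path <- system.file("extdata", file, package = "abnet")
  if (!nzchar(path) || !file.exists(path))
    stop("packaged fixture missing: ", file, call. = FALSE)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", quote = "")
  if (table == 2) {
    for (g in c("H", "BBP", "BC")) x[[g]] <- as.numeric(x[[g]])
  } else if (table == 3) {
    for (cc in c("node", "N", "rank")) x[[cc]] <- as.integer(x[[cc]])
    for (cc in c("M", "I")) x[[cc]] <- as.numeric(x[[cc]])
    tot_path <- system.file("extdata", "table3_totals.tsv",
                            package = "abnet")
    attr(x, "totals") <- utils::read.table(tot_path, header = TRUE,
                                           sep = "\t",
                                           stringsAsFactors = FALSE)
  } else {
    x$node <- as.integer(x$node)
    x$n_lost <- as.integer(x$n_lost)
    x$lost_partners[is.na(x$lost_partners)] <- ""
  }
  x
}

#' Split a comma-joined partner list into integer ids
#'
#' Helper for the table 4 fixture and for ledger files written by
#' [disconnection_ledger()] / [run_pipeline()].
#'
#' @param s character vector of comma-joined id lists (may be empty strings).
#' @return A list of integer vectors, one per element of `s`.
#' @export
parse_partner_list <- function(s) {
  lapply(s, function(x) {
    if (is.na(x) || !nzchar(trimws(x))) return(integer(0))
    as.integer(strsplit(trimws(x), "[,[:space:]]+")[[1]])
  })
}
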