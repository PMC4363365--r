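# Differential (link-loss) comparison of two group networks.
#
# Entrywise codes over the two adjacency matrices a (first group) and b
# (second group):
#   a = 1, b = 0  ->  2   (link lost going from a to b)
#   a = 0, b = 1  ->  1   (link gained)
#   otherwise     ->  0
# The disconnection table collects, per node, the partners of its code-2
# entries.

#' Entrywise disconnection codes between two networks
#'
#' @param b_a adjacency (`band_adj`) of the first group.
#' @param b_b adjacency of the second group; must share band ids.
#' @return Integer matrix of codes 0/1/2 (dimnames = band ids).
#' @examples
#' ch <- correlation_matrix(generate_cohort(synthetic_config(30, 8, seed = 1)))
#' cb <- correlation_matrix(generate_cohort(synthetic_config(30, 8, seed = 2)))
#' codes <- disconnection_codes(binarize(ch), binarize(cb))
#' table(codes[upper.tri(codes)])
#' @export
disconnection_codes <- function(b_a, b_b) {
  stopifnot(inherits(b_a, "band_adj"), inherits(b_b, "band_adj"))
  if (!identical(b_a$band_ids, b_b$band_ids))
    stop("the two networks have different band ids", call. = FALSE)
  codes <- 2L * (b_a$b == 1L & b_b$b == 0L) +
    1L * (b_a$b == 0L & b_b$b == 1L)
  dimnames(codes) <- list(b_a$band_ids, b_a$band_ids)
  codes
}

#' Disconnection ledger between two group networks
#'
#' Lists, per node, the partners whose link is present in the first
#' group's network and absent from the second's (code 2), together with
#' the gained links (code 1). Nodes are ordered by descending loss count,
#' ties by ascending band id; nodes with no losses are retained with empty
#' lists.
#'
#' Two tabulation styles are available. `"per_node"` (default) lists every
#' lost pair in both endpoints' rows, so each unordered pair appears
#' twice and the counts are true per-node disconnection degrees.
#' `"pairs_once"` lists each lost pair exactly once, under its
#' lower-numbered node -- the style of the published disconnection table,
#' whose per-node counts are therefore lower-node-attributed.
#'
#' @param b_a,b_b adjacencies (`band_adj`) sharing band ids; losses are
#'   links of `b_a` absent from `b_b`.
#' @param tabulation `"per_node"` or `"pairs_once"`.
#' @return data.frame of class `disconnection_ledger` with columns `node`,
#'   `n_lost`, `lost_partners` (comma-joined ids), and for `"per_node"`
#'   also `n_gained`, `gained_partners`. The comparison label is attached
#'   as attribute `comparison`.
#' @export
disconnection_ledger <- function(b_a, b_b,
                                 tabulation = c("per_node", "pairs_once")) {
  tabulation <- match.arg(tabulation)
  codes <- disconnection_codes(b_a, b_b)
  ids <- b_a$band_ids
  keep <- if (tabulation == "pairs_once") upper.tri(codes)
          else !diag(nrow(codes))
  lost <- codes == 2L & keep
  gained <- codes == 1L & keep
  join <- function(row) paste(ids[row], collapse = ",")
  out <- data.frame(
    node = ids,
    n_lost = as.integer(rowSums(lost)),
    lost_partners = vapply(seq_along(ids),
                           function(i) join(lost[i, ]), character(1)))
  if (tabulation == "per_node") {
    out$n_gained <- as.integer(rowSums(gained))
    out$gained_partners <- vapply(seq_along(ids),
                                  function(i) join(gained[i, ]),
                                  character(1))
  }
  out <- out[order(-out$n_lost, out$node), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "comparison") <- c(b_a$group, b_b$group)
  attr(out, "tabulation") <- tabulation
  class(out) <- c("disconnection_ledger", "data.frame")
  out
}
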