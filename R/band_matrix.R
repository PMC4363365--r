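#' Construct a binary band matrix
#'
#' A band matrix holds the presence (1) / absence (0) calls of immunoblot
#' bands: one row per participant serum, one column per band. Bands are
#' identified by the integer labels used throughout the reference tables
#' (1..121 in the original study); columns are stored in ascending band id
#' order regardless of input order.
#'
#' @param values numeric/integer matrix of 0/1 entries, participants in rows.
#' @param band_ids integer band labels, one per column, unique.
#' @param participant_ids character ids, one per row, unique. Defaults to
#'   `"P1"`, `"P2"`, ...
#' @param group group label (e.g. `"H"`, `"BBP"`, `"BC"`, or any string).
#' @return An object of class `band_matrix`: a list with elements `values`
#'   (integer matrix with dimnames), `band_ids`, `participant_ids`, `group`
#'   and `n` (participant count).
#' @examples
#' m <- band_matrix(matrix(c(1, 0, 0, 1, 1, 1), nrow = 3), band_ids = c(2, 7))
#' m$n
#' @export
band_matrix <- function(values, band_ids = seq_len(ncol(values)),
                        participant_ids = NULL, group = "unlabelled") {
  values <- as.matrix(values)
  if (is.null(participant_ids)) {
    participant_ids <- if (!is.null(rownames(values))) rownames(values)
                       else sprintf("P%d", seq_len(nrow(values)))
  }
  band_ids <- as.integer(band_ids)
  participant_ids <- as.character(participant_ids)
  if (length(band_ids) != ncol(values))
    stop("band_ids length (", length(band_ids), ") != number of columns (",
         ncol(values), ")", call. = FALSE)
  if (length(participant_ids) != nrow(values))
    stop("participant_ids length != number of rows", call. = FALSE)
  if (anyDuplicated(band_ids))
    stop("duplicate band ids: ",
         paste(unique(band_ids[duplicated(band_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(participant_ids))
    stop("duplicate participant ids", call. = FALSE)
  bad <- which(!(values %in% c(0, 1)) | is.na(values), arr.ind = FALSE)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(values))
    stop("non-binary value ", values[bad[1]], " at row ", rc[1],
         " (", participant_ids[rc[1]], "), band ", band_ids[rc[2]],
         call. = FALSE)
  }
  ord <- order(band_ids)
  values <- matrix(as.integer(values[, ord, drop = FALSE]),
                   nrow = nrow(values), ncol = length(band_ids),
                   dimnames = list(participant_ids, band_ids[ord]))
  structure(
    list(values = values, band_ids = band_ids[ord],
         participant_ids = participant_ids,
         group = as.character(group)[1], n = nrow(values)),
    class = "band_matrix")
}

#' @export
print.band_matrix <- function(x, ...) {
  cat("band_matrix: group ", x$group, ", ", x$n, " participants x ",
      length(x$band_ids), " bands, prevalence ",
      sprintf("%.2f", mean(x$values)), "\n", sep = "")
  invisible(x)
}

#' Read a band matrix from delimited text
#'
#' Expects a header row whose first column is `participant_id` and whose
#' remaining columns are integer band ids; cells must be 0 or 1. The
#' delimiter (comma or tab) is sniffed from the header line.
#'
#' @param path file path.
#' @param group group label attached to the result.
#' @return A [band_matrix].
#' @seealso [write_band_matrix()]
#' @export
read_band_matrix <- function(path, group = "unlabelled") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("expected a participant_id column plus at least one band column",
         call. = FALSE)
  ids <- df[[1L]]
  band_names <- colnames(df)[-1L]
  band_ids <- suppressWarnings(as.integer(band_names))
  if (anyNA(band_ids))
    stop("non-integer band id in header: ",
         paste(band_names[is.na(band_ids)], collapse = ", "), call. = FALSE)
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df), ncol = ncol(df) - 1L)
  band_matrix(vals, band_ids = band_ids, participant_ids = ids,
              group = group)
}

#' Write a band matrix to tab-delimited text
#'
#' The output round-trips through [read_band_matrix()]: a header of
#' `participant_id` plus band ids, then one 0/1 row per participant.
#'
#' @param m a [band_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(m, path) {
  stopifnot(inherits(m, "band_matrix"))
  df <- data.frame(participant_id = m$participant_ids,
                   m$values, check.names = FALSE)
  colnames(df) <- c("participant_id", m$band_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
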