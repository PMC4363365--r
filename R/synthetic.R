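# Correlated-binary cohort generator.
#
# Latent Gaussian (copula) model: participant i draws
#   z_ij = sqrt(rho_b) g_i + sqrt(rho_w - rho_b) h_{i,block(j)}
#          + sqrt(1 - rho_w) e_ij
# so cor(z_ij, z_ij') = rho_w within a block and rho_b across blocks, and
# band j is present iff z_ij exceeds the standard-normal quantile matching
# its marginal prevalence. Thresholding attenuates the realized phi
# coefficient below the latent rho; downstream tests therefore compare
# orderings and calibrations, never rho itself.

#' Configuration for a synthetic binary cohort
#'
#' @param n_participants sera per cohort (study shape: 50).
#' @param n_bands number of bands (study shape: 121).
#' @param blocks list of integer vectors partitioning `1:n_bands` into
#'   latent-clone blocks. Default: consecutive blocks of ~`block_size`.
#' @param rho_within latent correlation inside a block, in `[0, 1)`.
#' @param rho_between latent correlation across blocks, in
#'   `[0, rho_within]`.
#' @param prevalence per-band marginal presence probability, strictly in
#'   (0,1); a scalar is recycled. `NULL` draws band prevalences uniformly
#'   from 0.1--0.6 (reproducibly from `seed`), emulating the mix of rare
#'   and common bands seen on immunoblots.
#' @param seed integer seed; the full (config, seed) pair determines the
#'   cohort bit-for-bit.
#' @param block_size used only when `blocks` is `NULL`.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants = 50, n_bands = 121,
                             blocks = NULL, rho_within = 0.35,
                             rho_between = 0, prevalence = NULL,
                             seed = 1L, block_size = 10) {
  n_participants <- as.integer(n_participants)
  n_bands <- as.integer(n_bands)
  stopifnot(n_participants >= 1, n_bands >= 2)
  if (is.null(blocks)) {
    blocks <- split(seq_len(n_bands),
                    ceiling(seq_len(n_bands) / block_size))
    names(blocks) <- NULL
  }
  ids <- sort(unlist(blocks, use.names = FALSE))
  if (!identical(as.integer(ids), seq_len(n_bands)))
    stop("blocks must partition 1:", n_bands, " exactly", call. = FALSE)
  if (!(rho_between >= 0 && rho_between <= rho_within && rho_within < 1))
    stop("implied latent correlation is not positive definite: need ",
         "0 <= rho_between (", rho_between, ") <= rho_within (",
         rho_within, ") < 1", call. = FALSE)
  if (is.null(prevalence)) {
    prevalence <- with_seed(seed, stats::runif(n_bands, 0.1, 0.6))
  }
  prevalence <- rep_len(as.numeric(prevalence), n_bands)
  if (any(prevalence <= 0 | prevalence >= 1))
    stop("prevalence must lie strictly inside (0, 1)", call. = FALSE)
  structure(
    list(n_participants = n_participants, n_bands = n_bands,
         blocks = lapply(blocks, as.integer),
         rho_within = rho_within, rho_between = rho_between,
         prevalence = prevalence, seed = as.integer(seed)),
    class = "synthetic_config")
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Generate one binary cohort from a latent-Gaussian block model
#'
#' @param config a [synthetic_config()].
#' @param group group label attached to the returned matrix.
#' @return A [band_matrix] of size `n_participants` x `n_bands`.
#' @examples
#' cfg <- synthetic_config(n_participants = 20, n_bands = 10, seed = 7)
#' generate_cohort(cfg)
#' @export
generate_cohort <- function(config, group = "synthetic") {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_participants
  p <- config$n_bands
  rw <- config$rho_within
  rb <- config$rho_between
  block_of <- integer(p)
  for (k in seq_along(config$blocks)) block_of[config$blocks[[k]]] <- k
  vals <- with_seed(config$seed, {
    g <- stats::rnorm(n)                                  # shared factor
    h <- matrix(stats::rnorm(n * length(config$blocks)), nrow = n)
    e <- matrix(stats::rnorm(n * p), nrow = n)
    z <- sqrt(rb) * g +
      sqrt(rw - rb) * h[, block_of, drop = FALSE] +
      sqrt(1 - rw) * e
    thr <- stats::qnorm(1 - config$prevalence)
    (z > rep(thr, each = n)) + 0L
  })
  band_matrix(vals, band_ids = seq_len(p),
              participant_ids = sprintf("%s_%03d", group, seq_len(n)),
              group = group)
}

#' Per-group configurations inducing an ordering of network connectivity
#'
#' Produces one [synthetic_config()] per group, identical except for
#' `rho_within` (scaled to induce the requested ordering of expected link
#' counts, strongest first) and the seed (offset per group so cohorts are
#' independent).
#'
#' @param intensity_order group labels ordered from most to least
#'   connected, e.g. `c("BBP", "H", "BC")` for the study's ordering.
#' @param base the shared [synthetic_config()].
#' @param rho_within optional explicit per-group latent correlations
#'   (same length and order as `intensity_order`); must be non-increasing.
#' @param scale optional per-group multipliers of `base$rho_within`
#'   (default a linear fade from 1 to 0.4).
#' @return Named list of `synthetic_config` objects.
#' @examples
#' base <- synthetic_config(n_participants = 50, n_bands = 20, seed = 3)
#' cfgs <- group_scenario(c("BBP", "H", "BC"), base,
#'                        rho_within = c(0.5, 0.35, 0.2))
#' @export
group_scenario <- function(intensity_order, base, rho_within = NULL,
                           scale = NULL) {
  stopifnot(inherits(base, "synthetic_config"))
  k <- length(intensity_order)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  if (is.null(rho_within)) {
    if (is.null(scale)) scale <- seq(1, 0.4, length.out = k)
    rho_within <- base$rho_within * scale
  }
  if (length(rho_within) != k)
    stop("rho_within must match intensity_order in length", call. = FALSE)
  if (is.unsorted(rev(rho_within)))
    stop("rho_within must be non-increasing along intensity_order",
         call. = FALSE)
  cfgs <- lapply(seq_len(k), function(i) {
    synthetic_config(
      n_participants = base$n_participants, n_bands = base$n_bands,
      blocks = base$blocks, rho_within = rho_within[i],
      rho_between = min(base$rho_between, rho_within[i]),
      prevalence = base$prevalence, seed = base$seed + i - 1L)
  })
  names(cfgs) <- intensity_order
  cfgs
}

#' The default three-cohort study scenario
#'
#' Mirrors the study shape: groups BBP, H, BC of 50 sera each, 121 bands,
#' block-structured dependence whose strength decreases BBP > H > BC
#' (latent rho_within 0.5 / 0.35 / 0.2), band prevalences uniform on
#' 0.1--0.6.
#'
#' @param seed integer seed.
#' @return Named list of three [synthetic_config()] objects.
#' @export
default_scenario <- function(seed = 1L) {
  base <- synthetic_config(n_participants = 50, n_bands = 121,
                           rho_within = 0.5, rho_between = 0,
                           seed = seed)
  group_scenario(c("BBP", "H", "BC"), base,
                 rho_within = c(0.5, 0.35, 0.2))
}

#' Read a scenario description from a YAML file
#'
#' Keys match [synthetic_config()] arguments, plus optional `groups`
#' (labels, strongest first) and `group_rho_within` (per-group latent
#' correlations).
#'
#' @param path YAML file path.
#' @return Named list of `synthetic_config` objects (one group if no
#'   `groups` key).
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  base <- synthetic_config(
    n_participants = y$n_participants %||% 50,
    n_bands = y$n_bands %||% 121,
    blocks = y$blocks,
    rho_within = y$rho_within %||% 0.35,
    rho_between = y$rho_between %||% 0,
    prevalence = y$prevalence,
    seed = y$seed %||% 1L,
    block_size = y$block_size %||% 10)
  if (is.null(y$groups)) return(list(cohort = base))
  group_scenario(unlist(y$groups), base,
                 rho_within = unlist(y$group_rho_within))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
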