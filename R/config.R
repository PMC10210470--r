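#' Analysis configuration
#'
#' Bundles the knobs shared by the filtering and downstream statistics stages.
#' One global `rng_seed` governs every stochastic stage; each stage derives an
#' independent substream from it (see [stage_seed()]) so that running stages in
#' a different order cannot change results.
#'
#' @param pseudocount ALR smoothing constant; `NULL` (default) means half the
#'   smallest nonzero relative abundance of the table being transformed.
#' @param distance Dissimilarity used for ordination/PERMANOVA:
#'   `"manhattan"` (default) or `"bray_curtis"`.
#' @param n_permutations Monte-Carlo permutations for PERMANOVA (>= 1).
#' @param nmds_dimensions Target ordination dimensionality (>= 1).
#' @param nmds_restarts Random NMDS restarts.
#' @param rng_seed Global seed (integer).
#' @param alr_reference `"remainder"` (per-taxon log(x/(1-x)) analogue) or the
#'   name of a fixed reference taxon.
#' @param p_grid_resolution Grid step for the contaminant-proportion search,
#'   in (0, 0.1].
#' @return A classed list.
#' @export
analysis_config <- function(pseudocount = NULL,
                            distance = c("manhattan", "bray_curtis"),
                            n_permutations = 999L,
                            nmds_dimensions = 2L,
                            nmds_restarts = 20L,
                            rng_seed = 1L,
                            alr_reference = "remainder",
                            p_grid_resolution = 1e-3) {
  distance <- match.arg(distance)
  if (!is.null(pseudocount) && pseudocount <= 0) stop("pseudocount must be > 0")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (nmds_dimensions < 1) stop("nmds_dimensions must be >= 1")
  if (p_grid_resolution <= 0 || p_grid_resolution > 0.1)
    stop("p_grid_resolution must lie in (0, 0.1]")
  structure(list(pseudocount = pseudocount, distance = distance,
                 n_permutations = as.integer(n_permutations),
                 nmds_dimensions = as.integer(nmds_dimensions),
                 nmds_restarts = as.integer(nmds_restarts),
                 rng_seed = as.integer(rng_seed),
                 alr_reference = alr_reference,
                 p_grid_resolution = p_grid_resolution),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' The YAML fields mirror [analysis_config()] argument-for-argument; absent
#' fields fall back to the defaults.
#'
#' @param path YAML file path.
#' @return An `analysis_config` object.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(analysis_config, vals)
}

#' Derive a per-stage RNG substream seed
#'
#' Deterministic integer hash of the global seed and a stage label, kept below
#' 2^31 so it is always a valid `set.seed()` argument.
#'
#' @param seed Global integer seed.
#' @param stage Stage label (character) or index (integer).
#' @return A single integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(paste0(stage)) * seq_along(utf8ToInt(paste0(stage))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}
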