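#' Average negative-control profiles into a working control
#'
#' Low-biomass sorting runs carry a reagent/column background whose
#' compositional shape is stable across negative column controls; the filter
#' therefore works against a single averaged control profile. Absent taxa
#' count as zero in the mean, and the mean is renormalized to sum to 1.
#'
#' @param controls Either a list of relative-abundance profiles (named numeric
#'   vectors) or a count matrix of control columns (taxa x controls).
#' @return A `control_set`: list with `profiles` and `mean_profile`.
#' @export
average_controls <- function(controls) {
  if (is.matrix(controls)) {
    if (ncol(controls) == 0L) stop("no control columns supplied")
    controls <- lapply(colnames(controls), function(s) to_profile(controls, s))
  }
  if (!length(controls)) stop("no control profiles supplied")
  controls <- lapply(controls, function(p) {
    if (is.null(names(p))) stop("control profiles must be named vectors")
    p
  })
  taxa <- Reduce(union, lapply(controls, names))
  aligned <- vapply(controls, function(p) {
    v <- stats::setNames(numeric(length(taxa)), taxa)
    v[names(p)] <- p
    v
  }, numeric(length(taxa)))
  aligned <- matrix(aligned, nrow = length(taxa), dimnames = list(taxa, NULL))
  m <- rowMeans(aligned)
  if (sum(m) <= 0) stop("all control profiles are zero")
  structure(list(profiles = controls, mean_profile = m / sum(m)),
            class = "control_set")
}

#' Contaminant-mixture objective function
#'
#' The sum-of-squares criterion `sum_i (p * obsCont[i] - (1-p) * obsExp[i])^2`
#' scored over the taxa present in the control profile. Taxa found only in the
#' experimental sample are excluded so that genuine (non-contaminant) taxa
#' carry no mismatch penalty; taxa in the control but absent from the sample
#' enter with abundance zero. The objective is 0 exactly when a scaling of the
#' control's shape overlaps the sample's shape on the control support — in
#' particular a sample identical to the control minimizes to 0.
#'
#' @param p Mixture proportion(s) in \[0, 1\] (vectorized).
#' @param obs_exp Observed experimental profile (named numeric, sums to 1).
#' @param obs_cont Observed (averaged) control profile.
#' @return Objective value(s), finite and >= 0.
#' @export
mixture_objective <- function(p, obs_exp, obs_cont) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  idx <- names(obs_cont)[obs_cont > 0]
  cc <- obs_cont[idx]
  ee <- stats::setNames(numeric(length(idx)), idx)
  shared <- intersect(idx, names(obs_exp))
  ee[shared] <- obs_exp[shared]
  vapply(p, function(pp) sum((pp * cc - (1 - pp) * ee)^2), numeric(1L))
}

#' Estimate the contaminant proportion of one sample
#'
#' Minimizes [mixture_objective()] over p in \[0, 1\] by a dense grid at
#' `resolution` followed by golden-section refinement inside the best bracket.
#' Grid ties break toward the smaller p (less aggressive filtering). When the
#' sample shares no taxa with the control there is no evidence of
#' contamination and `p_hat = 0` with objective 0 is returned.
#'
#' @param obs_exp Observed experimental profile; must not be all zero.
#' @param control A `control_set` from [average_controls()], or a bare control
#'   profile (named numeric vector).
#' @param resolution Grid step (default 1e-3).
#' @return A `mixture_fit`: list with `p_hat`, `objective_value`,
#'   `shared_taxa`, `n_shared`.
#' @export
estimate_contaminant_proportion <- function(obs_exp, control, resolution = 1e-3) {
  obs_cont <- if (inherits(control, "control_set")) control$mean_profile else control
  if (sum(obs_exp) <= 0) stop("all-zero experimental profile: exclude empty samples before fitting")
  support <- names(obs_cont)[obs_cont > 0]
  shared <- intersect(support, names(obs_exp)[obs_exp > 0])
  if (!length(shared)) {
    return(structure(list(p_hat = 0, objective_value = 0,
                          shared_taxa = character(0L), n_shared = 0L),
                     class = "mixture_fit"))
  }
  grid <- seq(0, 1, by = resolution)
  if (grid[length(grid)] < 1) grid <- c(grid, 1)
  vals <- mixture_objective(grid, obs_exp, obs_cont)
  i <- which.min(vals)           # first minimum = smaller p on ties
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- .golden_section(function(pp) mixture_objective(pp, obs_exp, obs_cont), lo, hi)
  # keep whichever of grid point / refined point scores lower (ties -> smaller p)
  cand_p <- c(min(grid[i], opt$x), max(grid[i], opt$x))
  cand_v <- mixture_objective(cand_p, obs_exp, obs_cont)
  j <- which.min(cand_v)
  structure(list(p_hat = cand_p[j], objective_value = cand_v[j],
                 shared_taxa = shared, n_shared = length(shared)),
            class = "mixture_fit")
}

# golden-section minimization on [lo, hi]; objective is smooth (quadratic in p)
.golden_section <- function(f, lo, hi, tol = 1e-9, maxit = 200L) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  for (k in seq_len(maxit)) {
    if (b - a < tol) break
    if (f1 <= f2) { b <- c2; c2 <- c1; f2 <- f1; c1 <- b - gr * (b - a); f1 <- f(c1) }
    else          { a <- c1; c1 <- c2; f1 <- f2; c2 <- a + gr * (b - a); f2 <- f(c2) }
  }
  x <- (a + b) / 2
  list(x = x, value = f(x))
}

#' Subtract the estimated contaminant contribution from a profile
#'
#' For each taxon the filtered pre-normalization value is
#' `max(obsExp[i] - p * obsCont[i], 0)`: taxa absent from the control pass
#' through untouched, and a subtraction that would go negative is clamped to
#' zero. The clamped vector is renormalized to sum to 1; if every taxon is
#' removed the all-zero sentinel is returned.
#'
#' @param obs_exp Observed experimental profile (named numeric vector).
#' @param obs_cont Control profile.
#' @param p Contaminant proportion in \[0, 1\].
#' @return Filtered profile over the taxa of `obs_exp`.
#' @export
subtract_contaminant <- function(obs_exp, obs_cont, p) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  cont <- stats::setNames(numeric(length(obs_exp)), names(obs_exp))
  shared <- intersect(names(obs_exp), names(obs_cont))
  cont[shared] <- obs_cont[shared]
  raw <- pmax(obs_exp - p * cont, 0)
  s <- sum(raw)
  if (s <= 0) return(stats::setNames(numeric(length(obs_exp)), names(obs_exp)))
  raw / s
}

#' Rescale a sample's read depth after filtering
#'
#' The estimated contaminant proportion scales down the read depth so the
#' number of reads surviving the filter can be estimated:
#' `round(depth * (1 - p))` with half-away-from-zero rounding.
#'
#' @param depth Read depth (non-negative integer).
#' @param p Contaminant proportion in \[0, 1\].
#' @return Integer scaled depth, `<= depth`.
#' @export
scale_read_depth <- function(depth, p) {
  if (depth < 0) stop("depth must be >= 0")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  as.integer(floor(depth * (1 - p) + 0.5))
}

# integer counts from a profile: largest-remainder apportionment so the
# column sums exactly to `total`
.apportion <- function(profile, total) {
  if (total <= 0 || sum(profile) <= 0)
    return(stats::setNames(integer(length(profile)), names(profile)))
  target <- profile / sum(profile) * total
  base <- floor(target)
  k <- total - sum(base)
  if (k > 0) {
    extra <- order(target - base, decreasing = TRUE)[seq_len(k)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(profile))
}

#' Distribution-based contaminant filtering of a count table
#'
#' The package's fitting function. For every experimental sample it estimates
#' the mixture proportion `p` of the averaged negative-control profile by
#' least squares ([estimate_contaminant_proportion()]), subtracts `p` times
#' the control profile with clamping at zero, renormalizes, rescales the read
#' depth by `1 - p`, and emits integer counts apportioned so each column sums
#' exactly to its scaled depth. Zero-read samples are carried through
#' unfiltered but flagged, and excluded from fitting.
#'
#' @param counts Experimental count matrix (taxa x samples); validated via
#'   [taxa_count_table()].
#' @param controls Negative-control count matrix, list of control profiles, or
#'   a ready `control_set`.
#' @param config An [analysis_config()]; `p_grid_resolution` is the only field
#'   used here.
#' @return An object of class `decontamix` with components `counts` (input),
#'   `filtered` (integer matrix, same shape), `fits` (one row per sample:
#'   `sample_id`, `p_hat`, `objective`, `n_shared`, `depth_in`, `depth_out`,
#'   `fully_removed`, `zero_depth`), `control` (the `control_set`) and
#'   `config`. Supports `print`, `summary`, `coef` (p-hat per sample),
#'   `fitted` (filtered counts), `residuals` (mixture reconstruction error)
#'   and `plot`.
#' @examples
#' counts <- matrix(c(600L, 200L, 200L), ncol = 1,
#'                  dimnames = list(c("A", "X", "Y"), "s1"))
#' ctrl <- list(c(X = 0.5, Y = 0.5))
#' fit <- decontamix(counts, ctrl)
#' coef(fit)          # ~0.286: a third of the sample's reads match the control
#' fitted(fit)[, 1]   # A 600, X 57, Y 57 at depth 714
#' @export
decontamix <- function(counts, controls, config = analysis_config()) {
  counts <- taxa_count_table(counts)
  control <- if (inherits(controls, "control_set")) controls else average_controls(controls)
  overlap_any <- length(intersect(rownames(counts)[rowSums(counts) > 0],
                                  names(control$mean_profile)[control$mean_profile > 0])) > 0
  if (ncol(counts) > 0 && !overlap_any)
    warning("no experimental taxon overlaps the control profile; output is the identity")
  filtered <- counts
  fits <- data.frame(sample_id = colnames(counts), p_hat = NA_real_,
                     objective = NA_real_, n_shared = NA_integer_,
                     depth_in = as.integer(colSums(counts)),
                     depth_out = NA_integer_, fully_removed = FALSE,
                     zero_depth = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(counts))) {
    depth <- fits$depth_in[j]
    if (depth == 0L) {
      fits$zero_depth[j] <- TRUE
      fits$depth_out[j] <- 0L
      next
    }
    prof <- to_profile(counts, colnames(counts)[j])
    fit <- estimate_contaminant_proportion(prof, control, config$p_grid_resolution)
    filt <- subtract_contaminant(prof, control$mean_profile, fit$p_hat)
    d_out <- scale_read_depth(depth, fit$p_hat)
    fits$p_hat[j] <- fit$p_hat
    fits$objective[j] <- fit$objective_value
    fits$n_shared[j] <- fit$n_shared
    fits$depth_out[j] <- d_out
    fits$fully_removed[j] <- sum(filt) == 0
    filtered[, j] <- .apportion(filt, d_out)
  }
  structure(list(counts = counts, filtered = filtered, fits = fits,
                 control = control, config = config),
            class = "decontamix")
}

#' @export
print.decontamix <- function(x, ...) {
  n_fit <- sum(!x$fits$zero_depth)
  cat("Distribution-based contaminant filter\n")
  cat(sprintf("  %d taxa, %d samples (%d fitted, %d zero-read)\n",
              nrow(x$counts), ncol(x$counts), n_fit, sum(x$fits$zero_depth)))
  cat(sprintf("  control support: %d taxa from %d control profile(s)\n",
              sum(x$control$mean_profile > 0), length(x$control$profiles)))
  if (n_fit > 0) {
    p <- x$fits$p_hat[!x$fits$zero_depth]
    cat(sprintf("  p-hat: median %.3f, range [%.3f, %.3f]\n",
                stats::median(p), min(p), max(p)))
    cat(sprintf("  reads removed: %.1f%% of %d\n",
                100 * (1 - sum(x$fits$depth_out) / sum(x$fits$depth_in)),
                sum(x$fits$depth_in)))
  }
  invisible(x)
}

#' @export
summary.decontamix <- function(object, ...) {
  f <- object$fits
  structure(list(fits = f,
                 p_summary = summary(f$p_hat[!f$zero_depth]),
                 n_fully_removed = sum(f$fully_removed),
                 n_zero = sum(f$zero_depth),
                 reads_in = sum(f$depth_in), reads_out = sum(f$depth_out)),
            class = "summary.decontamix")
}

#' @export
print.summary.decontamix <- function(x, ...) {
  cat("Per-sample contaminant proportion (p-hat):\n")
  print(x$p_summary)
  cat(sprintf("fully removed samples: %d; zero-read samples: %d\n",
              x$n_fully_removed, x$n_zero))
  cat(sprintf("total reads: %d in, %d out\n", x$reads_in, x$reads_out))
  invisible(x)
}

#' @export
coef.decontamix <- function(object, ...)
  stats::setNames(object$fits$p_hat, object$fits$sample_id)

#' @export
fitted.decontamix <- function(object, ...) object$filtered

#' Mixture reconstruction residuals
#'
#' For each sample, the observed profile minus its fitted mixture
#' `(1 - p) * filtered_profile + p * control_profile`; small residuals mean
#' the two-component mixture explains the observed composition well.
#'
#' @param object A `decontamix` fit.
#' @param ... Unused.
#' @return Numeric matrix, taxa x samples (NA columns for zero-read samples).
#' @export
residuals.decontamix <- function(object, ...) {
  obs <- to_profiles(object$counts)
  filt <- to_profiles(object$filtered)
  cont <- stats::setNames(numeric(nrow(obs)), rownames(obs))
  shared <- intersect(rownames(obs), names(object$control$mean_profile))
  cont[shared] <- object$control$mean_profile[shared]
  res <- obs
  for (j in seq_len(ncol(obs))) {
    p <- object$fits$p_hat[j]
    res[, j] <- if (is.na(p)) NA_real_ else obs[, j] - ((1 - p) * filt[, j] + p * cont)
  }
  res
}

#' @export
plot.decontamix <- function(x, ...) {
  f <- x$fits[!x$fits$zero_depth, ]
  graphics::barplot(f$p_hat, names.arg = f$sample_id, las = 2,
                    ylab = "estimated contaminant proportion", ylim = c(0, 1), ...)
  invisible(x)
}
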