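#' Additive log-ratio transform
#'
#' Maps relative abundances onto an unconstrained scale for linear modeling:
#' `ALR_i = log((x_i + eps) / (x_ref + eps))`. Under the default
#' `"remainder"` policy the reference for each taxon is the pooled remainder
#' `1 - x_i`, giving every taxon a self-contained log-ratio (taxa are tested
#' one at a time downstream); alternatively a fixed reference taxon may be
#' named, whose own ALR is then identically 0.
#'
#' @param x A profile (named numeric vector summing to 1) or a taxa-by-sample
#'   matrix of relative abundances.
#' @param eps Pseudocount (> 0); `NULL` means half the smallest nonzero
#'   abundance in `x`.
#' @param reference `"remainder"` or the name of a taxon in `x`.
#' @return Same shape as `x`, ALR values.
#' @export
alr_transform <- function(x, eps = NULL, reference = "remainder") {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1L, dimnames = list(names(x), NULL)) else x
  if (is.null(eps)) {
    nz <- m[m > 0]
    if (!length(nz)) stop("cannot derive a pseudocount from an all-zero table")
    eps <- min(nz) / 2
  }
  if (eps < 0 || (eps == 0 && reference == "remainder" && any(m >= 1)))
    stop("eps must be > 0")
  if (identical(reference, "remainder")) {
    out <- log((m + eps) / ((1 - m) + eps))
  } else {
    if (!reference %in% rownames(m)) stop("reference taxon absent: ", reference)
    out <- sweep(log(m + eps), 2L, log(m[reference, ] + eps), "-")
  }
  if (vec) out[, 1L] else out
}

# exact null distribution of the signed-rank statistic under ties, by
# generating-function convolution over doubled (integer) ranks; identical to
# enumerating all 2^n sign patterns
.signrank_exact_p <- function(w, r) {
  s <- as.integer(round(2 * r))
  total <- sum(s)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (si in s) {
    g <- numeric(total + 1L)
    g[(si + 1L):(total + 1L)] <- f[1L:(total + 1L - si)]
    f <- f + g
  }
  f <- f / sum(f)
  w2 <- 2 * w
  support <- 0:total
  p_ge <- sum(f[support >= w2 - 1e-9])
  p_le <- sum(f[support <= w2 + 1e-9])
  min(1, 2 * min(p_ge, p_le))
}

.signrank_normal_p <- function(w, r) {
  mu <- sum(r) / 2
  sigma <- sqrt(sum(r^2) / 4)
  z <- (w - mu - sign(w - mu) * 0.5) / sigma
  2 * stats::pnorm(-abs(z))
}

#' Paired Wilcoxon signed-rank tests per taxon
#'
#' Tests, taxon by taxon, whether the ALR abundance differs between the two
#' fractions of each pair (e.g. IgG-bound minus raw). Zero differences are
#' dropped (Wilcoxon convention), tied absolute differences share average
#' ranks, the null is exact for up to 25 informative pairs (computed by
#' convolution over the tied ranks, equivalent to enumerating every sign
#' pattern) and a normal approximation with continuity correction beyond.
#' Benjamini-Hochberg q-values are reported across taxa.
#'
#' @param alr_bound,alr_raw Taxa-by-sample ALR matrices with identical taxa.
#' @param pairs Optional data.frame with columns `bound` and `raw` naming the
#'   paired columns; by default columns are paired by position.
#' @return data.frame: `taxon`, `n_pairs` (informative), `statistic` (W+),
#'   `p`, `q`, `direction`.
#' @export
paired_wilcoxon_by_taxon <- function(alr_bound, alr_raw, pairs = NULL) {
  if (!identical(rownames(alr_bound), rownames(alr_raw)))
    stop("taxa of the two ALR tables differ")
  if (is.null(pairs)) {
    if (ncol(alr_bound) != ncol(alr_raw)) stop("unequal sample counts and no pairs given")
    b <- alr_bound; r <- alr_raw
  } else {
    b <- alr_bound[, pairs$bound, drop = FALSE]
    r <- alr_raw[, pairs$raw, drop = FALSE]
  }
  res <- lapply(rownames(b), function(tx) {
    d <- b[tx, ] - r[tx, ]
    d <- d[is.finite(d) & d != 0]
    n <- length(d)
    if (n < 3L)
      return(data.frame(taxon = tx, n_pairs = n, statistic = NA_real_,
                        p = NA_real_, direction = "none", stringsAsFactors = FALSE))
    rk <- rank(abs(d))
    w <- sum(rk[d > 0])
    p <- if (n <= 25L) .signrank_exact_p(w, rk) else .signrank_normal_p(w, rk)
    dir <- if (w > n * (n + 1) / 4) "up" else if (w < n * (n + 1) / 4) "down" else "none"
    data.frame(taxon = tx, n_pairs = n, statistic = w, p = p, direction = dir,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (any(is.na(out$p)))
    warning(sum(is.na(out$p)), " taxon/taxa with fewer than 3 informative pairs: NA")
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[, c("taxon", "n_pairs", "statistic", "p", "q", "direction")]
}

#' Covariate-adjusted regression of paired ALR differences
#'
#' Fits, for every taxon, an ordinary least-squares model of the per-pair ALR
#' difference on a shared design (group plus covariates such as sex, age and
#' pack-years), i.e. the multivariate response is handled as parallel
#' per-taxon regressions with an identical design matrix. The group
#' coefficient's p-values are Benjamini-Hochberg adjusted across taxa.
#'
#' @param alr_diff Taxa-by-participant matrix of ALR differences.
#' @param covariates data.frame, one row per participant (column order matches
#'   the columns of `alr_diff`), containing `group_var` and any adjustment
#'   covariates; all its columns enter the design.
#' @param group_var Name of the grouping column whose coefficient is the
#'   target of inference.
#' @return An `alr_regression`: list with matrices `coefficients`, `se`, `t`,
#'   `p` (terms x taxa), vector `r_squared`, the `group_term` used, and
#'   `table` — a per-taxon data.frame (`taxon`, `estimate`, `se`, `t`, `p`,
#'   `q`, `r_squared`) for the group coefficient.
#' @export
alr_difference_regression <- function(alr_diff, covariates, group_var = "group") {
  if (!group_var %in% names(covariates)) stop("missing grouping column: ", group_var)
  if (nrow(covariates) != ncol(alr_diff))
    stop("covariate rows must match alr_diff columns")
  X <- stats::model.matrix(~ ., data = covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; aliased columns: ", paste(aliased, collapse = ", "))
  }
  Y <- t(alr_diff)
  fit <- stats::lm.fit(X, Y)
  cf <- fit$coefficients                      # terms x taxa
  if (is.null(dim(cf)))
    cf <- matrix(cf, ncol = 1L, dimnames = list(names(cf), rownames(alr_diff)))
  res <- matrix(fit$residuals, nrow = nrow(X),
                dimnames = list(NULL, rownames(alr_diff)))
  n <- nrow(X); pcol <- ncol(X)
  sigma2 <- colSums(res^2) / (n - pcol)
  xtxi <- chol2inv(qr.R(qx))
  se <- sqrt(outer(diag(xtxi), sigma2))
  dimnames(se) <- dimnames(cf)
  tval <- cf / se
  pval <- 2 * stats::pt(-abs(tval), df = n - pcol)
  tss <- colSums(sweep(Y, 2L, colMeans(Y))^2)
  r2 <- ifelse(tss > 0, 1 - colSums(res^2) / tss, 1)
  gcols <- grep(paste0("^", group_var), colnames(X), value = TRUE)
  if (!length(gcols)) stop("group term dropped from design: ", group_var)
  gterm <- gcols[1L]
  tab <- data.frame(taxon = colnames(cf), estimate = cf[gterm, ], se = se[gterm, ],
                    t = tval[gterm, ], p = pval[gterm, ],
                    q = stats::p.adjust(pval[gterm, ], method = "BH"),
                    r_squared = r2, row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = cf, se = se, t = tval, p = pval,
                 r_squared = r2, group_term = gterm, table = tab),
            class = "alr_regression")
}

#' @export
print.alr_regression <- function(x, ...) {
  cat("Per-taxon OLS of ALR differences; group term:", x$group_term, "\n")
  cat(sprintf("  %d taxa; %d with q < 0.05\n", nrow(x$table), sum(x$table$q < 0.05)))
  invisible(x)
}

#' Between-sample dissimilarity matrix
#'
#' Manhattan (`sum |x_i - y_i|`) or Bray-Curtis
#' (`sum |x_i - y_i| / sum (x_i + y_i)`) dissimilarities on relative
#' abundances. Count input is converted to profiles first; all-zero samples
#' are dropped with a warning (they have no composition).
#'
#' @param x Taxa-by-sample matrix of counts or relative abundances.
#' @param metric `"manhattan"` (default) or `"bray_curtis"`.
#' @return A `dist` object with attribute `metric`.
#' @export
distance_matrix <- function(x, metric = c("manhattan", "bray_curtis")) {
  metric <- match.arg(metric)
  p <- if (any(colSums(x) > 1 + 1e-6)) to_profiles(taxa_count_table(x)) else as.matrix(x)
  empty <- colSums(p) == 0
  if (any(empty)) {
    warning("dropping all-zero sample(s): ", paste(colnames(p)[empty], collapse = ", "))
    p <- p[, !empty, drop = FALSE]
  }
  d <- vegan::vegdist(t(p), method = if (metric == "manhattan") "manhattan" else "bray")
  attr(d, "metric") <- metric
  d
}

# sum over groups of within-group squared distances, each scaled by 1/n_g
.ss_within <- function(D2, labels) {
  s <- 0
  for (g in unique(labels)) {
    idx <- labels == g
    s <- s + sum(D2[idx, idx]) / (2 * sum(idx))
  }
  s
}

# all distinct label vectors of a grouping (multiset permutations)
.all_labelings <- function(labels) {
  rec <- function(counts, n) {
    if (n == 0L) return(list(integer(0L)))
    out <- list()
    for (g in seq_along(counts)) {
      if (counts[g] == 0L) next
      cc <- counts; cc[g] <- cc[g] - 1L
      out <- c(out, lapply(rec(cc, n - 1L), function(tl) c(g, tl)))
    }
    out
  }
  lev <- unique(labels)
  cnt <- as.integer(table(factor(labels, levels = lev)))
  lapply(rec(cnt, length(labels)), function(v) lev[v])
}

#' Permutational multivariate analysis of variance
#'
#' Partitions the sum of squared dissimilarities between and within groups:
#' `SS_total = (1/n) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`, pseudo-F =
#' `(SS_between/(k-1)) / (SS_within/(n-k))`, with significance by permuting
#' group labels. When the number of distinct relabelings is at most
#' `exact_limit` the full set is enumerated and the p-value is the exact
#' fraction of relabelings (the observed one included) with `F >= F_obs`;
#' otherwise `p = (1 + #[F_perm >= F_obs]) / (1 + n_permutations)`, so p is
#' never zero. With `covariates` the partition follows the Gower-centered
#' inner-product matrix with sequential (Type-I) sums of squares, covariates
#' entered before group, and permutation of raw observations.
#'
#' @param d A `dist` or symmetric distance matrix.
#' @param grouping Group labels (factor or character), one per sample.
#' @param covariates Optional data.frame of adjustment covariates (one row per
#'   sample) entered before `grouping`.
#' @param n_permutations Monte-Carlo permutations when enumeration is not used.
#' @param seed Optional seed for the permutation stream.
#' @param exact_limit Enumerate exhaustively when the number of distinct
#'   relabelings (or raw permutations, for the covariate model) is at most
#'   this.
#' @return A `permanova` object: `table` (term, df, SS, pseudo_F, R2, p),
#'   `n_permutations`, `method`, and `permuted_F` (quantile summary).
#' @export
permanova <- function(d, grouping, covariates = NULL, n_permutations = 999L,
                      seed = NULL, exact_limit = 10000L) {
  D <- as.matrix(d)
  n <- nrow(D)
  grouping <- as.character(grouping)
  if (length(grouping) != n) stop("grouping length must match the distance matrix")
  sizes <- table(grouping)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L)) stop("group of size 1: ", names(sizes)[sizes < 2L][1L])
  if (is.null(covariates)) {
    .permanova_onefactor(D, grouping, n_permutations, seed, exact_limit)
  } else {
    .permanova_covariates(D, grouping, covariates, n_permutations, seed, exact_limit)
  }
}

.permanova_onefactor <- function(D, grouping, n_permutations, seed, exact_limit) {
  D2 <- D^2
  n <- nrow(D); k <- length(unique(grouping))
  sst <- sum(D2) / (2 * n)
  ssw <- .ss_within(D2, grouping)
  ssb <- sst - ssw
  f_obs <- (ssb / (k - 1)) / (ssw / (n - k))
  sizes <- as.integer(table(grouping))
  log_n_lab <- lgamma(n + 1) - sum(lgamma(sizes + 1))
  exact <- log_n_lab <= log(exact_limit)
  if (exact) {
    labs <- .all_labelings(grouping)
    f_perm <- vapply(labs, function(l) {
      w <- .ss_within(D2, l)
      ((sst - w) / (k - 1)) / (w / (n - k))
    }, numeric(1L))
    p <- mean(f_perm >= f_obs - 1e-12)
    n_perm <- length(labs)
    method <- "exact enumeration"
  } else {
    if (!is.null(seed)) set.seed(seed)
    f_perm <- vapply(seq_len(n_permutations), function(b) {
      w <- .ss_within(D2, sample(grouping))
      ((sst - w) / (k - 1)) / (w / (n - k))
    }, numeric(1L))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_permutations)
    n_perm <- n_permutations
    method <- "monte carlo"
  }
  tab <- data.frame(term = c("group", "residual", "total"),
                    df = c(k - 1L, n - k, n - 1L),
                    SS = c(ssb, ssw, sst),
                    pseudo_F = c(f_obs, NA, NA),
                    R2 = c(ssb / sst, ssw / sst, 1),
                    p = c(p, NA, NA), stringsAsFactors = FALSE)
  structure(list(table = tab, n_permutations = n_perm, method = method,
                 permuted_F = stats::quantile(f_perm, c(0, 0.5, 0.9, 0.95, 0.99, 1))),
            class = "permanova")
}

.permanova_covariates <- function(D, grouping, covariates, n_permutations, seed,
                                  exact_limit) {
  n <- nrow(D)
  if (nrow(covariates) != n) stop("covariate rows must match the distance matrix")
  A <- -0.5 * D^2
  G <- sweep(sweep(A, 1L, rowMeans(A)), 2L, colMeans(A)) + mean(A)
  df_dat <- cbind(covariates, .group = factor(grouping))
  terms <- c(names(covariates), ".group")
  proj <- function(X) X %*% chol2inv(chol(crossprod(X))) %*% t(X)
  P_prev <- matrix(1 / n, n, n)
  df_prev <- 1L
  Ms <- list(); dfs <- integer(0L)
  for (tm in terms) {
    X <- stats::model.matrix(stats::reformulate(terms[seq_len(match(tm, terms))]),
                             data = df_dat)
    qx <- qr(X)
    P <- proj(X[, qx$pivot[seq_len(qx$rank)], drop = FALSE])
    Ms[[tm]] <- P - P_prev
    dfs[tm] <- qx$rank - df_prev
    P_prev <- P; df_prev <- qx$rank
  }
  M_res <- diag(n) - P_prev
  df_res <- n - df_prev
  ss_term <- vapply(Ms, function(M) sum(M * G), numeric(1L))
  ss_res <- sum(M_res * G)
  ss_tot <- sum(diag(G))
  f_stat <- (ss_term / dfs) / (ss_res / df_res)
  g_i <- ".group"
  f_obs <- f_stat[[g_i]]
  stat <- function(idx) {
    Gp <- G[idx, idx]
    (sum(Ms[[g_i]] * Gp) / dfs[[g_i]]) / (sum(M_res * Gp) / df_res)
  }
  if (lgamma(n + 1) <= log(exact_limit)) {
    perms <- .all_permutations(n)
    f_perm <- vapply(perms, stat, numeric(1L))
    p <- mean(f_perm >= f_obs - 1e-12)
    n_perm <- length(perms)
    method <- "exact enumeration"
  } else {
    if (!is.null(seed)) set.seed(seed)
    f_perm <- vapply(seq_len(n_permutations), function(b) stat(sample.int(n)),
                     numeric(1L))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_permutations)
    n_perm <- n_permutations
    method <- "monte carlo"
  }
  term_names <- c(names(covariates), "group")
  tab <- data.frame(term = c(term_names, "residual", "total"),
                    df = c(unname(dfs), df_res, n - 1L),
                    SS = c(unname(ss_term), ss_res, ss_tot),
                    pseudo_F = c(unname(f_stat), NA, NA),
                    R2 = c(unname(ss_term), ss_res, ss_tot) / ss_tot,
                    p = c(rep(NA, length(term_names) - 1L), p, NA, NA),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, n_permutations = n_perm, method = method,
                 permuted_F = stats::quantile(f_perm, c(0, 0.5, 0.9, 0.95, 0.99, 1))),
            class = "permanova")
}

.all_permutations <- function(n) {
  rec <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(rec(v[-i]), function(tl) c(v[i], tl)))
    out
  }
  rec(seq_len(n))
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (", x$method, ", ", x$n_permutations, " relabelings)\n", sep = "")
  tab <- x$table
  tab$SS <- signif(tab$SS, 6); tab$pseudo_F <- signif(tab$pseudo_F, 6)
  tab$R2 <- signif(tab$R2, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Non-metric multidimensional scaling
#'
#' Kruskal's stress-1 NMDS of a dissimilarity matrix (iterative monotone
#' regression, best of several random starts, via vegan's engine), with
#' centered coordinates and optional per-group centroids.
#'
#' @param d A `dist` or symmetric distance matrix.
#' @param k Target dimensionality (default 2); needs `n >= k + 2` samples.
#' @param restarts Random starts (best solution kept).
#' @param seed Optional seed.
#' @param grouping Optional labels for centroid computation.
#' @return An `nmds_ordination`: `points` (n x k), `stress` (stress-1),
#'   `converged` flag, `centroids` (group means of coordinates, or NULL).
#' @export
nmds <- function(d, k = 2L, restarts = 20L, seed = NULL, grouping = NULL) {
  D <- stats::as.dist(d)
  n <- attr(D, "Size")
  if (n < k + 2L) stop("need at least k + 2 samples")
  if (!is.null(seed)) set.seed(seed)
  m <- vegan::metaMDS(D, k = k, trymax = restarts, trace = 0,
                      autotransform = FALSE, wascores = FALSE)
  pts <- m$points
  colnames(pts) <- paste0("dim", seq_len(k))
  conv <- isTRUE(m$converged) || (is.numeric(m$converged) && m$converged > 0)
  centroids <- NULL
  if (!is.null(grouping)) {
    centroids <- apply(pts, 2L, function(col) tapply(col, grouping, mean))
    if (is.null(dim(centroids)))
      centroids <- matrix(centroids, nrow = 1L,
                          dimnames = list(unique(grouping), colnames(pts)))
  }
  structure(list(points = pts, stress = m$stress, converged = conv,
                 centroids = centroids, dimensions = k, restarts = restarts),
            class = "nmds_ordination")
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d samples in %d dimensions, stress-1 = %.4f (%s)\n",
              nrow(x$points), x$dimensions, x$stress,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

# Kruskal stress-1 of a configuration against target dissimilarities
.stress1 <- function(d, conf) {
  dd <- as.vector(stats::as.dist(d))
  dc <- as.vector(stats::dist(conf))
  o <- order(dd)
  dhat <- numeric(length(dc))
  dhat[o] <- stats::isoreg(dd[o], dc[o])$yf
  sqrt(sum((dc - dhat)^2) / sum(dc^2))
}

#' Log-log association between bacterial load and cytokine level
#'
#' Simple OLS of `log(cytokine)` on `log(load)` across participants, the
#' standard visualization-and-trend model for load-inflammation coupling.
#' Zeros are shifted by half the smallest positive value of their variable
#' before logging; incomplete pairs are dropped.
#'
#' @param load Per-participant bacterial quantity (qPCR 16S copies or
#'   flow-cytometry events).
#' @param cytokine Matching cytokine concentrations (pg/mL).
#' @return One-row data.frame: `slope`, `intercept`, `se`, `t`, `p`,
#'   `r_squared`, `n`.
#' @export
cytokine_association <- function(load, cytokine) {
  ok <- is.finite(load) & is.finite(cytokine) & load >= 0 & cytokine >= 0
  load <- load[ok]; cytokine <- cytokine[ok]
  shift <- function(v) {
    if (any(v == 0)) v[v == 0] <- min(v[v > 0]) / 2
    v
  }
  if (length(load) < 3L) stop("fewer than 3 complete pairs")
  x <- log(shift(load)); y <- log(shift(cytokine))
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  data.frame(slope = unname(stats::coef(fit)[2L]),
             intercept = unname(stats::coef(fit)[1L]),
             se = sm$coefficients[2L, 2L], t = sm$coefficients[2L, 3L],
             p = sm$coefficients[2L, 4L], r_squared = sm$r.squared,
             n = length(x))
}

#' Load-cytokine association table over a metadata frame
#'
#' Applies [cytokine_association()] to every `cytokine_*` column against every
#' available load measure (`qpcr_copies`, `flow_events`), one row per
#' participant (metadata rows are deduplicated by `pair_id`). Measures or
#' cytokines absent from the metadata are skipped with a warning.
#'
#' @param metadata A validated metadata data.frame (see [read_metadata()]).
#' @param measures Load columns to use when present.
#' @return data.frame: `cytokine`, `measure`, `slope`, `r_squared`, `p`, `n`.
#' @export
cytokine_association_table <- function(metadata,
                                       measures = c("qpcr_copies", "flow_events")) {
  md <- metadata[!duplicated(metadata$pair_id), ]
  cyts <- grep("^cytokine_", names(md), value = TRUE)
  measures_in <- intersect(measures, names(md))
  if (!length(cyts) || !length(measures_in)) {
    warning("no cytokine columns or no load measures in metadata; skipping association")
    return(data.frame(cytokine = character(0), measure = character(0),
                      slope = numeric(0), r_squared = numeric(0),
                      p = numeric(0), n = integer(0)))
  }
  out <- list()
  for (cy in cyts) for (ms in measures_in) {
    fit <- cytokine_association(md[[ms]], md[[cy]])
    out[[length(out) + 1L]] <- data.frame(cytokine = sub("^cytokine_", "", cy),
                                          measure = ms, slope = fit$slope,
                                          r_squared = fit$r_squared, p = fit$p,
                                          n = fit$n, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
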