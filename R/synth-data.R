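#' Build community and contaminant templates
#'
#' Defines the three compositional templates the cohort simulator draws from:
#' an oral-taxon-dominated unsorted (raw) BAL profile, a Pseudomonas-enriched
#' IgG-bound profile, and a reagent/column contaminant profile whose support
#' overlaps the community by a controllable fraction. Five anchor genera
#' (Streptococcus, Prevotella, Veillonella, Pseudomonas, Tropheryma) are
#' always present; remaining community weight is spread over common airway
#' genera and, for the contaminant, over typical kitome genera.
#'
#' @param n_taxa Number of community taxa (>= 5).
#' @param overlap Fraction of the contaminant support shared with the
#'   community, in \[0, 1\]. 0 gives a disjoint contaminant; 1 draws the whole
#'   contaminant support from community taxa.
#' @param seed Integer seed; output is deterministic given it.
#' @return A `community_template`: list with `taxa` (the full taxon universe),
#'   `base_raw`, `base_igg`, `contaminant` (profiles over `taxa`, each summing
#'   to 1) and `group_shift` (per-taxon log multiplier applied to the
#'   IgG-bound template of the shifted group).
#' @export
make_templates <- function(n_taxa = 30L, overlap = 0.3, seed = 1L) {
  if (n_taxa < 5L) stop("n_taxa must be >= 5")
  if (overlap < 0 || overlap > 1) stop("overlap must lie in [0, 1]")
  anchors <- c("Streptococcus", "Prevotella", "Veillonella", "Pseudomonas", "Tropheryma")
  pool <- c("Rothia", "Neisseria", "Haemophilus", "Fusobacterium", "Gemella",
            "Granulicatella", "Actinomyces", "Porphyromonas", "Leptotrichia",
            "Campylobacter", "Capnocytophaga", "Lactobacillus", "Staphylococcus",
            "Corynebacterium", "Moraxella")
  n_fill <- n_taxa - length(anchors)
  if (n_fill > length(pool))
    pool <- c(pool, sprintf("Taxon_%02d", seq_len(n_fill - length(pool))))
  community <- c(anchors, pool[seq_len(n_fill)])

  set.seed(stage_seed(seed, "templates"))
  fill_w <- function(total) {
    if (n_fill == 0L) return(numeric(0L))
    w <- stats::rgamma(n_fill, shape = 1.2) + 1e-4
    total * w / sum(w)
  }
  base_raw <- c(0.28, 0.20, 0.14, 0.02, 0.02, fill_w(0.34))
  base_igg <- c(0.12, 0.08, 0.05, 0.35, 0.08, fill_w(0.32))
  names(base_raw) <- names(base_igg) <- community

  m <- max(4L, round(0.4 * n_taxa))
  n_shared <- round(overlap * m)
  shared <- if (n_shared > 0) sample(community, n_shared) else character(0L)
  kitome <- c("Ralstonia", "Burkholderia", "Sphingomonas", "Bradyrhizobium",
              "Delftia", "Methylobacterium", "Cupriavidus", "Pelomonas",
              "Herbaspirillum", "Stenotrophomonas", "Phyllobacterium", "Variovorax")
  n_ded <- m - n_shared
  if (n_ded > length(kitome))
    kitome <- c(kitome, sprintf("Reagent_%02d", seq_len(n_ded - length(kitome))))
  cont_taxa <- c(shared, kitome[seq_len(n_ded)])
  cont_w <- stats::rgamma(m, shape = 1.2) + 1e-4
  contaminant <- stats::setNames(cont_w / sum(cont_w), cont_taxa)

  taxa <- union(community, cont_taxa)
  pad <- function(p) {
    v <- stats::setNames(numeric(length(taxa)), taxa)
    v[names(p)] <- p
    v
  }
  shift <- stats::setNames(numeric(length(taxa)), taxa)
  shift[c("Pseudomonas", "Tropheryma", "Streptococcus")] <- log(c(3, 2, 0.6))
  structure(list(taxa = taxa, base_raw = pad(base_raw), base_igg = pad(base_igg),
                 contaminant = pad(contaminant), group_shift = shift),
            class = "community_template")
}

#' Cohort simulation parameters
#'
#' Defaults mirror the study design the simulator emulates: 22 HIV-uninfected
#' and 42 PLWH participants, each contributing a paired raw / IgG-bound
#' sample; log-normal read depths (median 2e4, CV 0.6); Dirichlet
#' overdispersion theta = 50 for communities and 500 for the (stable)
#' contaminant; per-sample contaminant admixture p_true ~ Beta(2, 5); and
#' cytokines coupled to the IgG-bound bacterial load as
#' log(cytokine) = alpha + beta * log(load) + N(0, sigma).
#'
#' @param n_uninfected,n_plwh Participants per group.
#' @param depth_median,depth_cv Read-depth log-normal median and coefficient
#'   of variation.
#' @param theta,theta_contaminant Dirichlet concentrations (sample-to-sample
#'   overdispersion) for community and contaminant draws.
#' @param p_shape1,p_shape2 Beta parameters of the true admixture proportion.
#' @param cytokine_alpha,cytokine_beta,cytokine_sigma Log-linear cytokine
#'   coupling (intercept, slope, residual SD on the log scale).
#' @param n_controls,control_depth Negative-control columns and their depth.
#' @param seed Mandatory integer seed.
#' @return A classed parameter list.
#' @export
simulation_params <- function(n_uninfected = 22L, n_plwh = 42L,
                              depth_median = 2e4, depth_cv = 0.6,
                              theta = 50, theta_contaminant = 500,
                              p_shape1 = 2, p_shape2 = 5,
                              cytokine_alpha = log(20), cytokine_beta = 0.5,
                              cytokine_sigma = 0.3,
                              n_controls = 3L, control_depth = 1e4,
                              seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_uninfected >= 0, n_plwh >= 0, depth_median > 0, depth_cv > 0,
            theta > 0, theta_contaminant > 0, p_shape1 > 0, p_shape2 > 0,
            cytokine_sigma >= 0, n_controls >= 1, control_depth > 0)
  structure(list(n_uninfected = as.integer(n_uninfected), n_plwh = as.integer(n_plwh),
                 depth_median = depth_median, depth_cv = depth_cv,
                 theta = theta, theta_contaminant = theta_contaminant,
                 p_shape1 = p_shape1, p_shape2 = p_shape2,
                 cytokine_alpha = cytokine_alpha, cytokine_beta = cytokine_beta,
                 cytokine_sigma = cytokine_sigma,
                 n_controls = as.integer(n_controls), control_depth = control_depth,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

# Dirichlet draw; zero-concentration components stay exactly zero
.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) <= 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

.rdepth <- function(params) {
  sdlog <- sqrt(log(1 + params$depth_cv^2))
  max(1L, as.integer(round(stats::rlnorm(1, log(params$depth_median), sdlog))))
}

#' Simulate one participant's paired raw / IgG-bound samples
#'
#' Runs the contaminant mixture model forward: latent community profiles are
#' drawn Dirichlet around the templates, a latent contaminant profile around
#' the contaminant template, the observed composition is
#' `(1 - p_true) * actExp + p_true * actCont`, and counts are multinomial at a
#' log-normal depth. The multinomial draw of each fraction uses its own
#' derived seed (recorded in the truth rows) so observed counts can be
#' regenerated exactly from ground truth.
#'
#' @param template A [make_templates()] object.
#' @param params A [simulation_params()] object.
#' @param apply_shift Apply the template's group shift to the IgG-bound
#'   profile (TRUE for the shifted group)?
#' @param seed Integer seed for this pair.
#' @return List with `raw_counts`, `igg_counts` (named integer vectors over
#'   `template$taxa`), and `truth`: per-fraction `p_true`, `depth`,
#'   `count_seed`, plus `act_exp`, `act_cont`, `obs_exp` matrices.
#' @export
simulate_sample_pair <- function(template, params, apply_shift = FALSE, seed) {
  set.seed(seed)
  p_true <- stats::rbeta(2, params$p_shape1, params$p_shape2)  # raw, igg
  depth <- c(.rdepth(params), .rdepth(params))
  igg_base <- template$base_igg
  if (apply_shift) {
    igg_base <- igg_base * exp(template$group_shift)
    igg_base <- igg_base / sum(igg_base)
  }
  act_exp <- cbind(raw = .rdirichlet(params$theta * template$base_raw),
                   igg = .rdirichlet(params$theta * igg_base))
  act_cont <- cbind(raw = .rdirichlet(params$theta_contaminant * template$contaminant),
                    igg = .rdirichlet(params$theta_contaminant * template$contaminant))
  obs_exp <- sweep(act_exp, 2L, 1 - p_true, "*") + sweep(act_cont, 2L, p_true, "*")
  count_seed <- c(stage_seed(seed, "counts_raw"), stage_seed(seed, "counts_igg"))
  draw <- function(k) {
    set.seed(count_seed[k])
    stats::setNames(as.integer(stats::rmultinom(1, depth[k], obs_exp[, k])),
                    template$taxa)
  }
  list(raw_counts = draw(1L), igg_counts = draw(2L),
       truth = list(p_true = stats::setNames(p_true, c("raw", "igg")),
                    depth = stats::setNames(depth, c("raw", "igg")),
                    count_seed = stats::setNames(count_seed, c("raw", "igg")),
                    act_exp = act_exp, act_cont = act_cont, obs_exp = obs_exp))
}

#' Simulate cytokine concentrations coupled to bacterial load
#'
#' `log(cytokine) = alpha + beta * log(load) + Normal(0, sigma)`, one draw per
#' load value; concentrations are strictly positive.
#'
#' @param load Positive bacterial quantities (one per participant).
#' @param alpha,beta,sigma Coupling intercept, slope and log-scale noise SD.
#' @param seed Optional integer seed.
#' @return Cytokine concentrations (pg/mL scale), same length as `load`.
#' @export
simulate_cytokines <- function(load, alpha = log(20), beta = 0.5, sigma = 0.3,
                               seed = NULL) {
  if (any(load <= 0)) stop("load must be positive")
  if (sigma < 0) stop("sigma must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  exp(alpha + beta * log(load) + stats::rnorm(length(load), 0, sigma))
}

#' Simulate a full paired sorted-microbiome cohort
#'
#' Generates the complete inputs of the pipeline with known ground truth: a
#' taxa-by-sample count table of paired raw / IgG-bound fractions for two
#' participant groups (the group shift applies to the IgG-bound template of
#' the PLWH group only), negative-control columns drawn around the
#' contaminant template, a metadata table (demographics, cytokines, qPCR
#' copies, flow events), and a truth object sufficient to regenerate every
#' observed count column exactly.
#'
#' @param params A [simulation_params()] object.
#' @param template A [make_templates()] object.
#' @return A `cohort_sim`: list with `counts`, `controls` (integer matrices),
#'   `metadata` (data.frame as per [read_metadata()]), and `truth` (list:
#'   per-sample data.frame `samples`, matrices `act_exp`/`act_cont`/`obs_exp`,
#'   per-participant `loads`, the `params` and `template`).
#' @export
simulate_cohort <- function(params, template = make_templates(seed = params$seed)) {
  n <- params$n_uninfected + params$n_plwh
  taxa <- template$taxa
  pid <- sprintf("P%03d", seq_len(n))
  group <- rep(c("HIV_neg", "PLWH"), c(params$n_uninfected, params$n_plwh))

  set.seed(stage_seed(params$seed, "covariates"))
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.68, 0.32))
  age <- round(stats::runif(n, 35, 65))
  pack_years <- round(stats::rexp(n, rate = 1 / 9), 1)
  load <- stats::rlnorm(n, meanlog = log(1e4) + (group == "PLWH") * log(5), sdlog = 1)
  qpcr <- load * exp(stats::rnorm(n, 0, 0.2))
  flow <- round(load / 50 * exp(stats::rnorm(n, 0, 0.3)))
  il8 <- simulate_cytokines(load, params$cytokine_alpha, params$cytokine_beta,
                            params$cytokine_sigma, seed = stage_seed(params$seed, "IL8"))
  il1b <- simulate_cytokines(load, params$cytokine_alpha - log(4), params$cytokine_beta,
                             params$cytokine_sigma, seed = stage_seed(params$seed, "IL1b"))

  sample_ids <- as.vector(rbind(paste0(pid, "_raw"), paste0(pid, "_igg")))
  counts <- matrix(0L, nrow = length(taxa), ncol = 2L * n,
                   dimnames = list(taxa, if (n > 0) sample_ids else NULL))
  act_exp <- act_cont <- obs_exp <- matrix(NA_real_, length(taxa), 2L * n,
                                           dimnames = dimnames(counts))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pr <- simulate_sample_pair(template, params, apply_shift = group[i] == "PLWH",
                               seed = stage_seed(params$seed, paste0("pair_", pid[i])))
    j <- c(2L * i - 1L, 2L * i)
    counts[, j] <- cbind(pr$raw_counts, pr$igg_counts)
    act_exp[, j] <- pr$truth$act_exp
    act_cont[, j] <- pr$truth$act_cont
    obs_exp[, j] <- pr$truth$obs_exp
    rows[[i]] <- data.frame(sample_id = sample_ids[j], pair_id = pid[i],
                            fraction = c("raw", "igg_bound"), group = group[i],
                            p_true = unname(pr$truth$p_true),
                            depth = unname(pr$truth$depth),
                            count_seed = unname(pr$truth$count_seed),
                            stringsAsFactors = FALSE)
  }
  truth_samples <- if (n > 0) do.call(rbind, rows) else
    data.frame(sample_id = character(0), pair_id = character(0),
               fraction = character(0), group = character(0),
               p_true = numeric(0), depth = integer(0), count_seed = integer(0))

  set.seed(stage_seed(params$seed, "controls"))
  controls <- vapply(seq_len(params$n_controls), function(k) {
    prof <- .rdirichlet(params$theta_contaminant * template$contaminant)
    as.integer(stats::rmultinom(1, params$control_depth, prof))
  }, integer(length(taxa)))
  dimnames(controls) <- list(taxa, sprintf("NegCtrl_%d", seq_len(params$n_controls)))

  per_part <- data.frame(pair_id = pid, group = group, sex = sex, age = age,
                         pack_years = pack_years, cytokine_IL8 = il8,
                         cytokine_IL1b = il1b, qpcr_copies = qpcr,
                         flow_events = flow, stringsAsFactors = FALSE)
  metadata <- merge(truth_samples[, c("sample_id", "fraction", "pair_id")],
                    per_part, by = "pair_id", sort = FALSE)
  metadata <- metadata[match(truth_samples$sample_id, metadata$sample_id),
                       c("sample_id", "fraction", "pair_id", "group", "sex", "age",
                         "pack_years", "cytokine_IL8", "cytokine_IL1b",
                         "qpcr_copies", "flow_events")]
  rownames(metadata) <- NULL
  if (n > 0) validate_metadata(metadata)

  structure(list(counts = taxa_count_table(counts),
                 controls = taxa_count_table(controls),
                 metadata = metadata,
                 truth = list(samples = truth_samples, act_exp = act_exp,
                              act_cont = act_cont, obs_exp = obs_exp,
                              loads = data.frame(pair_id = pid, group = group,
                                                 load = load, stringsAsFactors = FALSE),
                              params = params, template = template)),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("Simulated paired sorted-microbiome cohort\n")
  cat(sprintf("  %d taxa, %d samples (%d participants), %d negative controls\n",
              nrow(x$counts), ncol(x$counts), nrow(x$truth$loads), ncol(x$controls)))
  if (nrow(x$truth$samples) > 0)
    cat(sprintf("  true contaminant admixture: median %.2f [%.2f, %.2f]\n",
                stats::median(x$truth$samples$p_true),
                min(x$truth$samples$p_true), max(x$truth$samples$p_true)))
  invisible(x)
}
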