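# fixtures are generated in code; no data files

random_profile <- function(n, seed = NULL, taxa = sprintf("T%02d", seq_len(n))) {
  if (!is.null(seed)) set.seed(seed)
  w <- rgamma(n, shape = 1)
  stats::setNames(w / sum(w), taxa)
}

# literal grid-search oracle for the mixture proportion: evaluates the printed
# objective term by term on a dense grid, then refines the winning bracket on
# a 1e-6 grid; independent of the package's optimizer
grid_oracle_p <- function(obs_exp, obs_cont, fine = 1e-6) {
  obj <- function(p) {
    idx <- names(obs_cont)[obs_cont > 0]
    s <- 0
    for (tx in idx) {
      e <- if (tx %in% names(obs_exp)) obs_exp[[tx]] else 0
      s <- s + (p * obs_cont[[tx]] - (1 - p) * e)^2
    }
    s
  }
  coarse <- seq(0, 1, by = 1e-3)
  v <- vapply(coarse, obj, numeric(1))
  i <- which.min(v)
  lo <- max(coarse[i] - 1e-3, 0); hi <- min(coarse[i] + 1e-3, 1)
  g <- seq(lo, hi, by = fine)
  vg <- vapply(g, obj, numeric(1))
  list(p = g[which.min(vg)], value = min(vg))
}

# closed-form argmin of the quadratic objective (independent algebraic oracle)
closed_form_p <- function(obs_exp, obs_cont) {
  idx <- names(obs_cont)[obs_cont > 0]
  cc <- obs_cont[idx]
  ee <- vapply(idx, function(tx) if (tx %in% names(obs_exp)) obs_exp[[tx]] else 0,
               numeric(1))
  A <- sum(cc^2); B <- sum(ee^2); C <- sum(cc * ee)
  min(1, max(0, (B + C) / (A + B + 2 * C)))
}

# random experimental/control profile pair over partially shared taxa
random_instance <- function(seed) {
  set.seed(seed)
  n_e <- sample(5:50, 1)
  n_c <- sample(5:50, 1)
  n_shared <- sample(0:min(n_e, n_c), 1)
  taxa_e <- sprintf("E%02d", seq_len(n_e))
  taxa_c <- c(taxa_e[seq_len(n_shared)],
              sprintf("C%02d", seq_len(n_c - n_shared)))
  list(obs_exp = random_profile(n_e, taxa = taxa_e),
       obs_cont = random_profile(n_c, taxa = taxa_c))
}

small_counts <- function() {
  matrix(c(5L, 5L, 0L, 10L), nrow = 2,
         dimnames = list(c("A", "B"), c("s1", "s2")))
}
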