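test_that("ALR transform matches hand arithmetic and compositional laws", {
  prof <- c(A = 0.2, B = 0.3, R = 0.5)
  fixed <- alr_transform(matrix(prof, ncol = 1, dimnames = list(names(prof), "s")),
                         eps = 1e-12, reference = "R")
  expect_equal(fixed["A", 1], log(0.4), tolerance = 1e-6)
  expect_equal(fixed["B", 1], log(0.6), tolerance = 1e-6)
  expect_equal(fixed["R", 1], 0)

  # scale invariance: multiplying counts by a constant before normalization
  set.seed(4)
  counts <- rpois(6, 50) + 1L
  p1 <- counts / sum(counts)
  p2 <- (7L * counts) / sum(7L * counts)
  names(p1) <- names(p2) <- sprintf("t%d", 1:6)
  expect_equal(alr_transform(p1, eps = 1e-6), alr_transform(p2, eps = 1e-6))

  # remainder policy: x/(1 - x) analogue, finite everywhere with eps > 0
  rem <- alr_transform(c(A = 0, B = 1), eps = 0.01)
  expect_true(all(is.finite(rem)))
  expect_error(alr_transform(prof, eps = 1e-3, reference = "Z"), "absent")
})

test_that("paired signed-rank test matches exhaustive sign-pattern enumeration", {
  d <- c(1, 2, 3, -1)
  mk <- function(v) matrix(v, nrow = 1, dimnames = list("tx", sprintf("s%d", seq_along(v))))
  res <- paired_wilcoxon_by_taxon(mk(d), mk(rep(0, 4)))
  expect_equal(res$statistic, 8.5)  # ties at |1| share rank 1.5

  # enumeration oracle over all 2^4 sign patterns
  r <- rank(abs(d))
  sums <- vapply(0:15, function(m) {
    bits <- as.integer(intToBits(m))[1:4]
    sum(r[bits == 1])
  }, numeric(1))
  p_oracle <- min(1, 2 * min(mean(sums >= 8.5), mean(sums <= 8.5)))
  expect_equal(res$p, p_oracle)

  # agreement with stats::wilcox.test on a tie-free case (exact path)
  set.seed(9)
  x <- rnorm(12); y <- rnorm(12)
  ours <- paired_wilcoxon_by_taxon(mk(x), mk(y))
  ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE, correct = FALSE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)

  # all-zero differences: no informative pairs, NA with warning
  expect_warning(zr <- paired_wilcoxon_by_taxon(mk(rep(1, 4)), mk(rep(1, 4))),
                 "informative")
  expect_true(is.na(zr$p))

  # invariance under reordering of taxa rows
  two <- rbind(a = c(0.4, 1.2, -0.7, 2.2, 0.3), b = c(1.1, -0.2, 0.5, 0.8, -1.4))
  colnames(two) <- sprintf("s%d", 1:5)
  zero <- two * 0
  r1 <- paired_wilcoxon_by_taxon(two, zero)
  r2 <- paired_wilcoxon_by_taxon(two[c("b", "a"), ], zero[c("b", "a"), ])
  expect_equal(r1[r1$taxon == "a", -1], r2[r2$taxon == "a", -1],
               ignore_attr = TRUE)
})

test_that("ALR-difference regression recovers exact fits and errors on aliasing", {
  set.seed(21)
  n <- 16
  cov <- data.frame(group = rep(c("ctl", "dis"), each = n / 2),
                    sex = sample(c("M", "F"), n, TRUE), age = runif(n, 30, 70))
  X <- model.matrix(~ ., cov)
  beta <- c(1, -2, 0.5, 0.03)
  y <- as.numeric(X %*% beta)                      # zero noise
  amat <- rbind(tx1 = y, tx2 = 2 * y)
  colnames(amat) <- sprintf("P%d", 1:n)
  fit <- alr_difference_regression(amat, cov)
  expect_equal(unname(fit$coefficients[, "tx1"]), beta, tolerance = 1e-10)
  expect_equal(unname(fit$r_squared), c(1, 1), tolerance = 1e-10)

  bad <- cov; bad$age2 <- bad$age * 2
  expect_error(alr_difference_regression(amat, bad), "aliased.*age2")

  # two points, one covariate: perfect fit, zero residual
  tiny <- alr_difference_regression(matrix(c(1, 3), 1, dimnames = list("t", NULL)),
                                    data.frame(group = c(0, 1)))
  expect_equal(tiny$r_squared[["t"]], 1)
})

test_that("null-group regression keeps the false-flag rate controlled", {
  set.seed(77)
  n <- 30; n_taxa <- 200
  cov <- data.frame(group = sample(rep(c("a", "b"), n / 2)),
                    age = runif(n, 30, 70))
  amat <- matrix(rnorm(n_taxa * n), nrow = n_taxa,
                 dimnames = list(sprintf("t%03d", 1:n_taxa), sprintf("P%d", 1:n)))
  fit <- alr_difference_regression(amat, cov)
  expect_lte(mean(fit$table$q < 0.05), 0.10)
  expect_true(all(fit$table$q >= fit$table$p))
})

test_that("distance matrices follow the closed forms and equivariance", {
  p <- cbind(s1 = c(A = 0.6, B = 0.4), s2 = c(A = 0.1, B = 0.9))
  expect_equal(as.matrix(distance_matrix(p))["s1", "s2"], 1.0)
  expect_equal(as.matrix(distance_matrix(p, "bray_curtis"))["s1", "s2"], 0.5)

  same <- cbind(s1 = c(A = 0.3, B = 0.7), s2 = c(A = 0.3, B = 0.7))
  expect_equal(as.matrix(distance_matrix(same))["s1", "s2"], 0)
  expect_equal(as.matrix(distance_matrix(same, "bray_curtis"))["s1", "s2"], 0)

  disj <- cbind(s1 = c(A = 1, B = 0), s2 = c(A = 0, B = 1))
  expect_equal(as.matrix(distance_matrix(disj))["s1", "s2"], 2)
  expect_equal(as.matrix(distance_matrix(disj, "bray_curtis"))["s1", "s2"], 1)

  # permutation equivariance on a random table
  set.seed(6)
  m <- matrix(rpois(40, 30), nrow = 5,
              dimnames = list(sprintf("t%d", 1:5), sprintf("s%d", 1:8)))
  d <- as.matrix(distance_matrix(m))
  perm <- sample(8)
  dp <- as.matrix(distance_matrix(m[, perm]))
  expect_equal(dp, d[perm, perm])

  # all-zero sample dropped with warning
  mz <- m; mz[, 3] <- 0L
  expect_warning(dz <- distance_matrix(mz), "all-zero")
  expect_equal(attr(dz, "Size"), 7L)
})

test_that("PERMANOVA reproduces the enumerable worked instance", {
  D <- dist(c(0, 1, 10, 11), method = "manhattan")
  res <- permanova(D, c("g1", "g1", "g2", "g2"))
  tab <- res$table
  expect_equal(tab$SS[tab$term == "total"], 101)
  expect_equal(tab$SS[tab$term == "residual"], 1)
  expect_equal(tab$pseudo_F[1], 200)
  expect_equal(tab$R2[1], 100 / 101)
  expect_equal(res$method, "exact enumeration")
  expect_equal(res$n_permutations, 6L)

  # independent enumeration oracle over all distinct labelings
  D2 <- as.matrix(D)^2
  sst <- sum(D2) / 8
  ssw_of <- function(lab) {
    s <- 0
    for (g in unique(lab)) {
      i <- lab == g
      s <- s + sum(D2[i, i]) / (2 * sum(i))
    }
    s
  }
  f_all <- apply(combn(4, 2), 2, function(id) {
    lab <- rep("b", 4); lab[id] <- "a"
    w <- ssw_of(lab)
    ((sst - w) / 1) / (w / 2)
  })
  p_oracle <- mean(f_all >= 200 - 1e-12)
  expect_equal(tab$p[1], p_oracle)     # = 1/3: the complementary labeling ties
  expect_equal(tab$p[1], 1 / 3)

  # cross-check against vegan's implementation with complete enumeration
  ref <- vegan::adonis2(D ~ g, data = data.frame(g = c("g1", "g1", "g2", "g2")),
                        permutations = permute::how(nperm = 23, complete = TRUE))
  expect_equal(tab$pseudo_F[1], ref$F[1])
  expect_equal(tab$R2[1], ref$R2[1])
  expect_equal(tab$p[1], ref$`Pr(>F)`[1], tolerance = 1e-12)
})

test_that("PERMANOVA invariants: decomposition, null behavior, MC consistency", {
  set.seed(14)
  m <- matrix(rpois(120, 40), nrow = 6,
              dimnames = list(sprintf("t%d", 1:6), sprintf("s%d", 1:20)))
  d <- distance_matrix(m)
  g <- rep(c("a", "b"), each = 10)
  res <- permanova(d, g, n_permutations = 999, seed = 3)
  tab <- res$table
  expect_equal(tab$R2[1] + tab$SS[2] / tab$SS[3], 1, tolerance = 1e-10)
  expect_gt(tab$p[1], 0)
  expect_lte(tab$p[1], 1)

  # vegan agreement on statistic and R2 (free permutation scheme)
  ref <- vegan::adonis2(d ~ g, data = data.frame(g = g), permutations = 99)
  expect_equal(tab$pseudo_F[1], ref$F[1], tolerance = 1e-10)
  expect_equal(tab$R2[1], ref$R2[1], tolerance = 1e-10)

  # two identical clouds: no group effect
  dup <- cbind(m, m)
  colnames(dup) <- sprintf("s%d", 1:40)
  resn <- permanova(distance_matrix(dup), rep(c("a", "b"), each = 20),
                    n_permutations = 999, seed = 4)
  expect_lt(resn$table$R2[1], 0.05)
  expect_gt(resn$table$p[1], 0.5)

  # exact vs Monte-Carlo agreement within binomial error (3 sigma)
  small <- m[, 1:8]
  ds <- distance_matrix(small)
  gs <- rep(c("a", "b"), each = 4)
  ex <- permanova(ds, gs)                       # 70 labelings, exact
  mc <- permanova(ds, gs, n_permutations = 10000, seed = 5, exact_limit = 1)
  p0 <- ex$table$p[1]
  se <- sqrt(p0 * (1 - p0) / 10000)
  expect_lt(abs(mc$table$p[1] - p0), 3 * se + 2e-4)

  # a group of size 1 is rejected
  expect_error(permanova(ds, c("a", rep("b", 7))), "size 1")
})

test_that("covariate-adjusted PERMANOVA matches vegan's sequential partition", {
  set.seed(25)
  m <- matrix(rpois(180, 40), nrow = 6,
              dimnames = list(sprintf("t%d", 1:6), sprintf("s%d", 1:30)))
  d <- distance_matrix(m)
  covs <- data.frame(age = runif(30, 30, 70), sex = sample(c("M", "F"), 30, TRUE))
  g <- rep(c("a", "b"), each = 15)
  res <- permanova(d, g, covariates = covs, n_permutations = 499, seed = 6)
  ref <- vegan::adonis2(d ~ age + sex + g,
                        data = cbind(covs, g = g), by = "terms", permutations = 99)
  expect_equal(res$table$SS[1:3], ref$SumOfSqs[1:3], tolerance = 1e-8)
  expect_equal(res$table$pseudo_F[3], ref$F[3], tolerance = 1e-8)
  expect_gt(res$table$p[3], 0)
})

test_that("NMDS embeds exactly embeddable configurations with near-zero stress", {
  set.seed(51)
  pts <- matrix(rnorm(20), ncol = 2)
  d <- dist(pts)
  ord <- nmds(d, k = 2, restarts = 10, seed = 1)
  expect_lte(ord$stress, 0.01)

  # unit square: recovered diagonal/side ratio ~ sqrt(2), centered coordinates
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  o2 <- nmds(dist(sq), k = 2, restarts = 10, seed = 2)
  expect_lt(o2$stress, 1e-3)
  rec <- as.matrix(dist(o2$points))
  ratio <- rec[1, 3] / rec[1, 2]
  expect_equal(ratio, sqrt(2), tolerance = 0.05)
  expect_equal(unname(colMeans(o2$points)), c(0, 0), tolerance = 1e-6)

  # stress is invariant under rotation/reflection/translation
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  moved <- sweep(o2$points %*% R, 2, c(3, -1), "+")
  s_fun <- decontamix:::.stress1
  expect_equal(s_fun(dist(sq), o2$points), s_fun(dist(sq), moved), tolerance = 1e-10)

  # centroids are the group means of member coordinates
  g <- c("u", "u", "v", "v")
  o3 <- nmds(dist(sq), k = 2, restarts = 10, seed = 3, grouping = g)
  expect_equal(o3$centroids["u", ], colMeans(o3$points[1:2, ]))
  expect_error(nmds(dist(sq), k = 3), "at least")
})

test_that("load-cytokine regression recovers exact and null couplings", {
  load <- exp(seq(1, 5, length.out = 20))
  fit <- cytokine_association(load, load)       # cytokine = load
  expect_equal(fit$slope, 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  set.seed(63)
  cy <- simulate_cytokines(rlnorm(42, 9, 1), beta = 0.5, sigma = 0.3, seed = 64)
  shuffled <- sample(cy)
  null_fit <- cytokine_association(rlnorm(42, 9, 1), shuffled)
  expect_lt(null_fit$r_squared, 0.1)

  expect_error(cytokine_association(c(1, 2), c(1, 2)), "fewer than 3")

  # table wrapper walks cytokine columns x measures
  md <- data.frame(sample_id = sprintf("s%d", 1:12),
                   fraction = rep(c("raw", "igg_bound"), 6),
                   pair_id = rep(sprintf("P%d", 1:6), each = 2), group = "g",
                   cytokine_IL8 = rep(exp(rnorm(6, 3)), each = 2),
                   qpcr_copies = rep(exp(rnorm(6, 9)), each = 2))
  tab <- cytokine_association_table(md)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n, 6L)
  expect_warning(cytokine_association_table(md[, 1:4]), "skipping")
})
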