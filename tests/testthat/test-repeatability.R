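test_that("PCA ordination: rank-1 data, duplicates, eigen oracle", {
  design <- make_design(n_lines = 2, tissues = "abdomen")  # 8 samples
  # samples on a line in gene space
  t_ <- seq(-2, 5, length.out = 8)
  dirv <- c(1, -2, 0.5)
  logcpm <- t(outer(t_, dirv)) + c(3, 1, 7)
  dimnames(logcpm) <- list(paste0("g", 1:3), design$sample)
  ord <- ordinate_pca(as_norm(logcpm, design), k = 3)
  expect_equal(ord$explained[1], 1, tolerance = 1e-9)
  expect_lt(sum(ord$explained[-1]), 1e-9)

  # duplicating every sample gives identical scores for duplicates
  design2 <- rbind(design, transform(design, sample = paste0(sample, "b"),
                                     line = line + 2))
  logcpm2 <- cbind(logcpm, logcpm)
  colnames(logcpm2) <- design2$sample
  ord2 <- ordinate_pca(as_norm(logcpm2, design2), k = 2)
  expect_equal(unname(ord2$scores[1:8, ]), unname(ord2$scores[9:16, ]),
               tolerance = 1e-9)

  # independent eigendecomposition oracle on a 6-sample, 2-gene toy
  set.seed(21)
  X <- matrix(rnorm(12), 6, 2)   # samples x genes
  logcpm3 <- t(X)
  design3 <- make_design(n_lines = 3, tissues = "abdomen", sexes = "F")
  dimnames(logcpm3) <- list(c("gA", "gB"), design3$sample)
  ord3 <- ordinate_pca(as_norm(logcpm3, design3), k = 2)
  eg <- eigen(cov(X))
  scores_oracle <- scale(X, center = TRUE, scale = FALSE) %*% eg$vectors
  for (j in 1:2) {  # eigenvectors are sign-ambiguous
    expect_equal(abs(unname(ord3$scores[, j])), abs(scores_oracle[, j]),
                 tolerance = 1e-9)
  }
  expect_equal(ord3$explained, eg$values / sum(eg$values), tolerance = 1e-9)

  expect_error(ordinate_pca(as_norm(logcpm3, design3), k = 7), "exceeds")
})

test_that("centroids are exact group means of member scores", {
  ds <- random_dataset(n_genes = 40, n_lines = 2, seed = 6)
  ord <- ordinate_pca(logcpm_matrix(ds), k = 5)
  key <- paste(ord$groups$regime, ord$groups$sex, ord$groups$tissue, sep = ".")
  for (g in unique(key)) {
    expect_equal(unname(ord$centroids[g, ]),
                 unname(colMeans(ord$scores[key == g, , drop = FALSE])))
  }
})

test_that("repeatability R = D/(D + d) with its boundary conventions", {
  norm <- half_disparity_norm()
  ord <- ordinate_pca(norm, k = 2)
  est <- repeatability_R(ord, "E", "F", "abdomen")
  expect_equal(est$D, 1, tolerance = 1e-12)
  expect_equal(est$d, 0.5, tolerance = 1e-12)
  expect_equal(est$R, 2 / 3, tolerance = 1e-12)

  # d = 0, D > 0 -> R = 1: replicates exactly on their centroid
  design <- make_design(n_lines = 4, tissues = "abdomen", sexes = "F")
  lc <- rbind(gA = rep(c(0, 1), each = 4), gB = 0)
  colnames(lc) <- design$sample
  est1 <- repeatability_R(ordination(t(lc), design), "E", "F", "abdomen")
  expect_equal(est1$R, 1)

  # D = 0 -> R = 0 (including the fully degenerate 0/0 case)
  lc0 <- matrix(0, 2, 8, dimnames = dimnames(lc))
  est0 <- repeatability_R(ordination(t(lc0), design), "E", "F", "abdomen")
  expect_equal(est0$R, 0)

  expect_error(repeatability_R(ord, "E", "M", "abdomen"), "no M samples|stratum")
})

test_that("R is invariant to rotation, translation and scaling of scores", {
  set.seed(31)
  design <- make_design(n_lines = 4, tissues = "abdomen", sexes = "F")
  for (rep_i in 1:5) {
    scores <- matrix(rnorm(8 * 3), 8, 3,
                     dimnames = list(design$sample, NULL))
    base <- repeatability_R(ordination(scores, design), "E", "F", "abdomen")
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))        # random rotation
    shift <- matrix(rnorm(3), 8, 3, byrow = TRUE)
    c_ <- runif(1, 0.1, 10)
    rot <- repeatability_R(ordination(scores %*% Q + shift, design),
                           "E", "F", "abdomen")
    scl <- repeatability_R(ordination(scores * c_, design), "E", "F", "abdomen")
    expect_equal(rot$R, base$R, tolerance = 1e-9)
    expect_equal(scl$R, base$R, tolerance = 1e-9)
  }
})

test_that("E and L estimates of a stratum share D but not d", {
  ds <- random_dataset(n_genes = 80, n_lines = 4, seed = 7)
  ord <- ordinate_pca(logcpm_matrix(ds), k = 10)
  eE <- repeatability_R(ord, "E", "F", "abdomen")
  eL <- repeatability_R(ord, "L", "F", "abdomen")
  expect_equal(eE$D, eL$D)
  expect_false(isTRUE(all.equal(eE$d, eL$d)))
})

test_that("gene bootstrap is deterministic and bounds the estimate", {
  sim <- simulate_dataset(sim_config(n_genes = 300, tissues = "abdomen",
                                     rng_seed = 8))
  norm <- logcpm_matrix(filter_genes(sim$dataset))
  a <- bootstrap_ci(norm, "E", "F", "abdomen", k = 10, n_boot = 120, seed = 5)
  b <- bootstrap_ci(norm, "E", "F", "abdomen", k = 10, n_boot = 120, seed = 5)
  expect_identical(a[c("R", "ci_low", "ci_high")], b[c("R", "ci_low", "ci_high")])
  expect_true(a$ci_low <= a$R && a$R <= a$ci_high)
  expect_true(a$ci_low >= 0 && a$ci_high <= 1)
  expect_error(bootstrap_ci(norm, "E", "F", "abdomen", n_boot = 50), "n_boot")

  # zero-variance data: degenerate CI [0, 0] without crashing
  design <- make_design(n_lines = 2, tissues = "abdomen", sexes = "F")
  flat <- matrix(5, 10, 4, dimnames = list(paste0("g", 1:10), design$sample))
  z <- bootstrap_ci(as_norm(flat, design), "E", "F", "abdomen",
                    k = 2, n_boot = 100, seed = 1)
  expect_equal(c(z$R, z$ci_low, z$ci_high), c(0, 0, 0))
})

test_that("strong divergence yields ci_low > 0.5 (5 seeds)", {
  hits <- 0
  for (sd_ in 1:5) {
    cfg <- sim_config(n_genes = 800, tissues = "abdomen", sigma_line = 0.1,
                      effect_size = list(kind = "fixed", value = 2),
                      frac_regime_de = 0.10, frac_interaction = 0,
                      rng_seed = sd_)
    sim <- simulate_dataset(cfg)
    norm <- logcpm_matrix(filter_genes(sim$dataset))
    est <- bootstrap_ci(norm, "E", "F", "abdomen", k = 15, n_boot = 100,
                        seed = sd_)
    hits <- hits + (est$ci_low > 0.5)
  }
  expect_gte(hits, 4)
})

test_that("sample-level bootstrap and fixed-ordination variants run", {
  sim <- simulate_dataset(sim_config(n_genes = 200, tissues = "abdomen",
                                     rng_seed = 9))
  norm <- logcpm_matrix(filter_genes(sim$dataset))
  s1 <- bootstrap_ci(norm, "E", "F", "abdomen", k = 8, n_boot = 100, seed = 2,
                     boot_unit = "samples")
  s2 <- bootstrap_ci(norm, "E", "F", "abdomen", k = 8, n_boot = 100, seed = 2,
                     boot_unit = "samples")
  expect_identical(s1[c("ci_low", "ci_high")], s2[c("ci_low", "ci_high")])
  f1 <- bootstrap_ci(norm, "E", "F", "abdomen", k = 8, n_boot = 100, seed = 2,
                     refit_pca = FALSE)
  expect_true(f1$ci_low >= 0 && f1$ci_high <= 1)
})
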