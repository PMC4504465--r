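test_that("patient clustering recovers the planted imaging patterns", {
  tab <- make_cohort_scores(c(50, 50, 50), score_noise_sd = 0.4, seed = 7)
  cl <- cluster_patients(tab, k = 3, region = "thigh", n_restarts = 20, seed = 11)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(cl$assignments, tab$true_cluster)
  expect_gte(ari, 0.9)
  # labels ordered mildest first
  sev <- vapply(1:3, function(k) mean(cl$features[cl$assignments == k, ]), numeric(1))
  expect_true(all(diff(sev) > 0))
})

test_that("noise-free archetypes are recovered exactly and k = 1 is the grand mean", {
  t0 <- make_cohort_scores(c(1, 1, 1), score_noise_sd = 0, seed = 2)
  cl <- cluster_patients(t0, k = 3, region = "thigh", n_restarts = 5, seed = 3)
  expect_equal(cl$inertia, 0)
  expect_equal(length(unique(cl$assignments)), 3)

  c1 <- cluster_patients(t0, k = 1, region = "thigh", seed = 3)
  expect_equal(as.numeric(c1$centers), unname(colMeans(c1$features)))

  expect_error(cluster_patients(t0, k = 5, region = "thigh", seed = 1), "invalid k")
})

test_that("small-cohort clustering attains the exhaustive partition optimum", {
  tab <- make_cohort_scores(c(3, 3, 2), score_noise_sd = 0.6, seed = 13)
  cl <- cluster_patients(tab, k = 3, region = "thigh", n_restarts = 20, seed = 5)
  X <- cl$features
  n <- nrow(X)
  best <- Inf
  grid <- as.matrix(expand.grid(rep(list(1:3), n)))
  for (r in seq_len(nrow(grid))) {
    a <- grid[r, ]
    ss <- 0
    for (g in unique(a)) {
      xg <- X[a == g, , drop = FALSE]
      ss <- ss + sum(sweep(xg, 2, colMeans(xg))^2)
    }
    if (ss < best) best <- ss
  }
  expect_equal(cl$inertia, best, tolerance = 1e-9)
})

test_that("asymmetry follows the one-grade bilateral difference rule", {
  arch <- cbind(thigh_archetypes(), leg_archetypes())
  tab <- make_cohort_scores(c(4, 3, 3), score_noise_sd = 0, seed = 1)
  # zero noise: sides identical, no asymmetry anywhere
  asym0 <- asymmetry_summary(tab)
  expect_equal(asym0$pct_patients_thigh, 0)

  # hand-built 10-patient table: exactly 9 have an asymmetric thigh pair
  tab$VM_L <- tab$VM_R + c(rep(1, 9), 0)
  asym <- asymmetry_summary(tab)
  expect_equal(asym$pct_patients_thigh, 90)
  expect_equal(asym$per_muscle$pct_asymmetric[asym$per_muscle$muscle == "VM"], 90)
  # pair (3, 2) asymmetric, (2, 2) symmetric by definition
  expect_true(abs(3 - 2) >= 1)
  expect_false(abs(2 - 2) >= 1)
})

test_that("ICC matches an independent variance-components oracle", {
  set.seed(41)
  for (rep in 1:6) {
    r <- matrix(rnorm(12, rep(rnorm(6, 10, 3), 2), 0.5), 6, 2)
    got <- icc_agreement(r)
    df <- data.frame(y = as.vector(r), s = factor(rep(1:6, 2)),
                     rt = factor(rep(1:2, each = 6)))
    ms <- anova(stats::aov(y ~ s + rt, df))[["Mean Sq"]]
    oracle <- (ms[1] - ms[3]) / (ms[1] + ms[3] + 2 * (ms[2] - ms[3]) / 6)
    expect_lt(abs(got$icc - oracle), 1e-10)
    expect_lte(got$icc, 1)
  }
})

test_that("identical rating columns give ICC exactly 1 and CV exactly 0", {
  r <- cbind(c(3, 7, 2, 9, 5), c(3, 7, 2, 9, 5))
  got <- icc_agreement(r)
  expect_identical(got$icc, 1)
  expect_identical(got$cv_mean, 0)
  expect_error(icc_agreement(matrix(5, 4, 2)), "degenerate")
})

test_that("a constant rater offset lowers absolute agreement below consistency", {
  set.seed(43)
  base <- rnorm(8, 20, 4)
  r <- cbind(base, base + 3)
  abs_icc <- icc_agreement(r, form = "absolute")$icc
  con_icc <- icc_agreement(r, form = "consistency")$icc
  expect_lt(abs_icc, con_icc)
  expect_equal(con_icc, 1, tolerance = 1e-12)
})

test_that("Spearman rho and exact permutation p match independent oracles", {
  x <- c(1, 2, 2, 3, 5, 6); y <- c(2, 1, 4, 4, 6, 5)
  got <- spearman_bonferroni(x, y)
  expect_equal(got$rho, unname(cor(rank(x), rank(y))))
  # exhaustive 720-permutation oracle, computed the slow way
  rx <- rank(x); ry <- rank(y)
  perms <- musclefat:::.permutations(6)
  rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
  expect_equal(got$p_raw, mean(abs(rhos) >= abs(got$rho) - 1e-12))
  expect_equal(got$method, "exact permutation")

  mono <- spearman_bonferroni(1:8, exp(1:8) + 1)
  expect_equal(mono$rho, 1)

  adj <- spearman_bonferroni(c(1, 3, 2, 5, 4, 6, 8, 7, 9, 10, 12, 11),
                             c(2, 3, 1, 6, 4, 5, 9, 7, 8, 11, 10, 12),
                             m_tests = 10)
  expect_equal(adj$p_adjusted, min(1, 10 * adj$p_raw))
  expect_equal(adj$method, "t approximation")
  expect_error(spearman_bonferroni(rep(1, 6), 1:6), "constant")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(44)
  x <- rnorm(15); y <- rnorm(15)
  a <- spearman_bonferroni(x, y)
  b <- spearman_bonferroni(exp(x), y)
  c2 <- spearman_bonferroni(x, y^3 + 5 * y)
  expect_equal(a$rho, b$rho)
  expect_equal(a$rho, c2$rho)
  expect_equal(a$p_raw, b$p_raw)
})

test_that("the pooled t-test has its symmetry and degenerate behaviour", {
  x <- c(1, 2, 3, 4)
  same <- two_sample_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  y <- c(2, 4, 6, 9)
  ab <- two_sample_t(x, y); ba <- two_sample_t(y, x)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
  expect_error(two_sample_t(c(1, 1), c(2, 2)), "degenerate")
})

test_that("exact functional forms are recovered by the R-squared comparison", {
  score <- seq(1, 4, length.out = 20)
  f_log <- exp(-3 + 0.8 * score)
  r1 <- linear_vs_log_r2(score, f_log)
  expect_equal(r1$r2_log, 1, tolerance = 1e-12)
  expect_lt(r1$r2_linear, 1)
  f_lin <- 0.02 + 0.1 * score
  r2 <- linear_vs_log_r2(score, f_lin)
  expect_equal(r2$r2_linear, 1, tolerance = 1e-12)
  expect_warning(linear_vs_log_r2(score, c(0, f_lin[-1])), "offset")
  expect_error(linear_vs_log_r2(rep(2, 5), f_lin[1:5]), "undefined fit")
})

test_that("STIR frequencies count muscles and patients correctly", {
  tab <- make_cohort_scores(c(5, 3, 2), stir_rate = 0, seed = 3)
  s0 <- stir_frequency(tab)
  expect_equal(s0$pct_muscles, 0)
  expect_equal(s0$pct_patients, 0)

  # 35 patients x 32 entries = 1120; flag 35 entries across 10 patients
  tab35 <- make_cohort_scores(c(16, 10, 9), stir_rate = 0, seed = 4)
  stir_cols <- grep("^stir_", names(tab35), value = TRUE)
  expect_equal(35 * length(stir_cols), 1120)
  k <- 0
  for (p in 1:10) {
    ncols <- if (p <= 5) 4 else 3  # 5*4 + 5*3 = 35 flags
    tab35[p, stir_cols[seq_len(ncols)]] <- 1
    k <- k + ncols
  }
  expect_equal(k, 35)
  s1 <- stir_frequency(tab35)
  expect_equal(s1$pct_muscles, 100 * 35 / 1120)  # 3.125 %
  expect_equal(s1$pct_patients, 100 * 10 / 35, tolerance = 1e-10)

  one <- make_cohort_scores(c(1), archetype_means = thigh_archetypes()[1, , drop = FALSE],
                            stir_rate = 0, seed = 5)
  one[1, "stir_VM_L"] <- 1
  s2 <- stir_frequency(one)
  expect_equal(s2$pct_muscles, 100 / 20)  # 1 of 20 thigh entries
  expect_equal(s2$pct_patients, 100)
})
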