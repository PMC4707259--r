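test_that("group_summary computes mean, SE and n per cell", {
  obs <- data.frame(g = rep(c("a", "b"), each = 4),
                    v = c(5, 5, 5, 5, 1, 2, 3, 4))
  s <- group_summary(obs, by = "g", var = "v")
  expect_equal(s$mean, c(5, 2.5))
  expect_equal(s$se, c(0, sd(1:4) / 2), tolerance = 1e-12)
  expect_equal(s$n, c(4L, 4L))
  # missing cells are absent, not zero
  obs2 <- obs[obs$g != "b", ]
  s2 <- group_summary(obs2, by = "g", var = "v")
  expect_equal(nrow(s2), 1L)
})

test_that("anova_lsd matches the closed-form LSD oracle", {
  # 3 genotypes, n = 4, residuals constructed with known MSE
  set.seed(3)
  g <- rep(c("g1", "g2", "g3"), each = 4)
  resid <- c(-1, 1, -1, 1, -1, 1, -1, 1, -1, 1, -1, 1) * sqrt(3) / 2
  y <- c(rep(0, 4), rep(5, 4), rep(10, 4)) + resid
  res <- anova_lsd(y, g)
  mse_oracle <- sum(tapply(y, g, function(x) sum((x - mean(x))^2))) / 9
  lsd_oracle <- qt(0.975, 9) * sqrt(2 * mse_oracle / 4)
  expect_equal(res$mse, mse_oracle, tolerance = 1e-12)
  expect_equal(res$lsd_05, lsd_oracle, tolerance = 1e-12)
  expect_false(res$protected)
  expect_equal(nrow(res$pairwise_significant), 3L)
})

test_that("LSD protection: no pairs reported when F is not significant", {
  # two clearly separated groups vs indistinguishable groups
  set.seed(4)
  y_sep <- c(rnorm(4, 0, 0.01), rnorm(4, 10, 0.01))
  g2 <- rep(c("a", "b"), each = 4)
  res_sep <- anova_lsd(y_sep, g2)
  expect_false(res_sep$protected)
  expect_equal(nrow(res_sep$pairwise_significant), 1L)
  y_null <- rnorm(8)
  res_null <- anova_lsd(y_null + mean(y_null), g2)
  if (res_null$f_pvalue > 0.05) {
    expect_true(res_null$protected)
    expect_equal(nrow(res_null$pairwise_significant), 0L)
  }
  expect_error(anova_lsd(c(1, 2), c("a", "b")), "2 replicates")
})

test_that("protection invariant holds on null data (family-wise rate)", {
  # 5 genotypes, n = 4, all from one distribution; the family-wise rate of
  # declaring any pair significant equals the ANOVA type-I rate
  set.seed(2024)
  n_sim <- 1000
  g <- rep(paste0("g", 1:5), each = 4)
  hits <- replicate(n_sim, {
    res <- anova_lsd(rnorm(20), g)
    nrow(res$pairwise_significant) > 0
  })
  mc_se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lte(mean(hits), 0.05 + 2 * mc_se)
})

test_that("pearson_matrix is symmetric with unit diagonal and flags", {
  x <- seq_len(10)
  m <- pearson_matrix(data.frame(a = x, b = -x, c = x^2))
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m, t(m))
  expect_equal(m["a", "b"], -1)
  expect_true(all(abs(m) <= 1 + 1e-12))
  expect_warning(pearson_matrix(data.frame(a = x, z = rep(1, 10))),
                 "zero variance")
})

test_that("pearson_matrix recovers a known latent correlation", {
  set.seed(5)
  n <- 500
  z <- rnorm(n)
  a <- 0.8 * z + sqrt(1 - 0.64) * rnorm(n)
  r <- pearson_matrix(data.frame(z = z, a = a))["z", "a"]
  expect_lt(abs(r - 0.8), 0.06)
})

test_that("density_folds computes per-plant, per-hill and efficiency folds", {
  obs <- data.frame(hill_density = rep(c(1, 4), each = 4),
                    total_zn_uptake_ug = c(rep(1, 4), rep(10, 4)),
                    root_dw_mg = c(rep(20, 4), rep(50, 4)))
  f <- density_folds(obs)
  expect_equal(f$uptake_fold[f$hill_density == 4], 10)
  expect_equal(f$root_dw_fold[f$hill_density == 4], 2.5)
  expect_equal(f$efficiency_fold[f$hill_density == 4], 4)
  expect_equal(f$uptake_per_hill_ug, f$uptake_ug * f$hill_density)
  # unit invariance
  obs2 <- obs
  obs2$total_zn_uptake_ug <- obs2$total_zn_uptake_ug * 1000
  expect_equal(density_folds(obs2)$efficiency_fold, f$efficiency_fold)
  # equal folds -> efficiency fold 1
  obs3 <- obs
  obs3$root_dw_mg <- c(rep(20, 4), rep(200, 4))
  expect_equal(density_folds(obs3)$efficiency_fold[2], 1)
  expect_error(density_folds(obs[obs$hill_density != 1, ]), "baseline")
})

test_that("percent_fine_roots handles plain and degenerate cases", {
  expect_equal(percent_fine_roots(50, 30, 20), 0.5)
  expect_equal(percent_fine_roots(0, 30, 20), 0)
  expect_equal(percent_fine_roots(1, 1, 1), 1 / 3)
  expect_warning(out <- percent_fine_roots(0, 0, 0), "zero total")
  expect_true(is.na(out))
  expect_error(percent_fine_roots(-1, 1, 1), "non-negative")
})

test_that("round_half_up rounds halves away from zero", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.5, -0.5)), c(1, 2, 3, -1))
  expect_equal(round_half_up(66.666667, 0), 67)
})
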