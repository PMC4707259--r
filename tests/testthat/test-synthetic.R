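test_that("noiseless field generation hits the group anchors exactly", {
  obs <- generate_field(sim_config(noise_cv = 0))
  at14 <- obs[obs$dat == 14, ]
  rsa <- tapply(at14$rsa_cm2, at14$group, mean)
  expect_equal(unname(rsa[["tolerant"]]), 88.0, tolerance = 1e-12)
  expect_equal(unname(rsa[["sensitive"]]), 70.7, tolerance = 1e-12)
  # uptake-estimation rule inverts the generator per plant
  obs2 <- add_total_uptake(obs)
  at28 <- obs2[obs2$dat == 28 & obs2$group == "tolerant", ]
  expect_equal(unique(round(at28$total_zn_uptake_ug, 9)),
               round(1.8 + (1.09 * exp(0.171 * 14) - 1.09), 9))
})

test_that("noiseless pipeline roundtrip recovers generating coefficients", {
  obs <- generate_field(sim_config(noise_cv = 0))
  fits <- fit_field_curves(obs, seedling_zn_ug = 1.8)
  expect_equal(fits$tolerant$uptake$rate, 0.171, tolerance = 1e-6)
  expect_equal(fits$tolerant$rsa$rate, 0.082, tolerance = 1e-6)
  expect_equal(fits$sensitive$uptake$rate, 0.150, tolerance = 1e-6)
  expect_equal(fits$sensitive$rsa$rate, 0.045, tolerance = 1e-6)
  expect_equal(fits$sensitive$rsa$scale, 108.1, tolerance = 1e-6)
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_field(sim_config(seed = 99))
  b <- generate_field(sim_config(seed = 99))
  expect_identical(a, b)
  d <- generate_density(sim_config(seed = 99))
  d2 <- generate_density(sim_config(seed = 99))
  expect_identical(d, d2)
  s <- generate_solution(sim_config(seed = 99))
  s2 <- generate_solution(sim_config(seed = 99))
  expect_identical(s, s2)
  # different seeds differ (with noise)
  expect_false(identical(generate_field(sim_config(seed = 1)),
                         generate_field(sim_config(seed = 2))))
})

test_that("noiseless density data reproduce the configured folds exactly", {
  dens <- add_total_uptake(generate_density(sim_config(noise_cv = 0)))
  f <- density_folds(dens)
  expect_equal(f$uptake_fold[f$hill_density == 4], 10, tolerance = 1e-12)
  expect_equal(f$root_dw_fold[f$hill_density == 4], 2.5, tolerance = 1e-12)
  expect_equal(f$efficiency_fold[f$hill_density == 4], 4, tolerance = 1e-12)
  # saturation at 8 plants per hill
  expect_equal(f$uptake_fold[f$hill_density == 8], 10, tolerance = 1e-12)
  # per-hill totals scale with density
  expect_equal(f$uptake_per_hill_ug, f$uptake_ug * f$hill_density)
  # switching the effects off removes them
  cfg0 <- sim_config(noise_cv = 0,
                     density_effects = list(uptake_fold_at_4 = 1,
                                            rootdw_fold_at_4 = 1,
                                            saturation_at_8 = TRUE))
  f0 <- density_folds(add_total_uptake(generate_density(cfg0)))
  expect_equal(f0$uptake_fold, rep(1, 4), tolerance = 1e-12)
})

test_that("solution generation honours targets and Zn conservation", {
  sol <- generate_solution(sim_config(noise_cv = 0))
  d0 <- sol[sol$dap == 0, ]
  tot0 <- tapply(d0$root_zn_ug + d0$shoot_zn_ug, d0$group, mean)
  expect_equal(unname(tot0[["tolerant"]]), 1.33, tolerance = 1e-12)
  expect_equal(unname(tot0[["sensitive"]]), 1.11, tolerance = 1e-12)
  # conservation per plant, also with noise: root gain <= shoot loss
  for (cv in c(0, 0.10)) {
    s <- generate_solution(sim_config(seed = 8, noise_cv = cv))
    key <- paste(s$genotype, s$replicate)
    s0 <- s[s$dap == 0, ]; s13 <- s[s$dap == 13, ]
    s13 <- s13[match(paste(s0$genotype, s0$replicate),
                     paste(s13$genotype, s13$replicate)), ]
    shoot_loss <- s0$shoot_zn_ug - s13$shoot_zn_ug
    expect_true(all(s13$root_zn_ug <= shoot_loss + 1e-12))
  }
})

test_that("noisy generation keeps pipeline estimates near the truth", {
  # 10% CV, n = 4: over 40 seeds the fitted uptake-rate median relative
  # error stays below 10% and the RE share at t1 = 7 stays within 0.08 of
  # the noiseless value (scaled down from 100 seeds to keep the suite fast;
  # the full-size check runs in test-acceptance.R)
  noiseless <- decompose_difference(ref_curves()$tolerant,
                                    ref_curves()$sensitive, 7)$re_share
  res <- vapply(1:40, function(s) {
    obs <- generate_field(sim_config(seed = s, noise_cv = 0.10))
    fits <- fit_field_curves(obs, seedling_zn_ug = 1.8)
    a <- decompose_difference(fits$tolerant, fits$sensitive, 7)
    c(rate_err = abs(fits$tolerant$uptake$rate - 0.171) / 0.171,
      re_share = a$re_share)
  }, numeric(2))
  expect_lt(median(res["rate_err", ]), 0.10)
  expect_lt(abs(median(res["re_share", ]) - noiseless), 0.08)
})

test_that("contamination option adds a spurious root conc column", {
  cfg <- sim_config(noise_cv = 0, contamination = c(30, 100))
  obs <- generate_field(cfg)
  expect_true(all(obs$root_zn_ug_per_g >= 30 & obs$root_zn_ug_per_g <= 100))
  expect_warning(add_total_uptake(obs), "contamination")
})
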