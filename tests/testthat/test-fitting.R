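ref_coef <- list(
  list(c(1.09, 0.171, 1.09), "uptake"),
  list(c(110.2, 0.082, 22.2), "rsa"),
  list(c(0.64, 0.150, 0.63), "uptake"),
  list(c(108.1, 0.045, 37.4), "rsa"))

test_that("three-point roundtrips recover the generating coefficients", {
  for (rc in ref_coef) {
    k <- rc[[1]]
    t3 <- c(0, 7, 14)
    s <- group_series("g", t3, k[1] * exp(k[2] * t3) - k[3], rc[[2]])
    f <- fit_exp(s)
    expect_true(f$converged)
    expect_equal(f$curve$rate, k[2], tolerance = 1e-6)
    expect_equal(f$curve$scale, k[1], tolerance = 1e-6)
    expect_equal(f$curve$offset, k[3], tolerance = 1e-5)
    expect_lt(f$rss, 1e-6 * max(s$values)^2)
    # predictions reproduce the data to 1e-8 relative
    pred <- eval_curve(f$curve, t3)
    expect_equal(pred, s$values, tolerance = 1e-8)
  }
})

test_that("degenerate inputs raise informative errors", {
  expect_error(group_series("g", c(0, 7), c(1, 2), "uptake"), "at least 3")
  expect_error(fit_exp(group_series("g", c(0, 7, 14), c(5, 5, 5), "uptake")),
               "constant series")
  expect_error(group_series("g", c(0, 7, 7), c(1, 2, 3), "uptake"),
               "strictly increasing")
})

test_that("fit is scale-equivariant", {
  set.seed(7)
  t5 <- c(0, 3, 7, 10, 14)
  y <- 2 * exp(0.12 * t5) - 1 + rnorm(5, sd = 0.05)
  f1 <- fit_exp(group_series("g", t5, y, "uptake"))
  f2 <- fit_exp(group_series("g", t5, 100 * y, "uptake"))
  expect_equal(f2$curve$rate, f1$curve$rate, tolerance = 1e-8)
  expect_equal(f2$curve$scale, 100 * f1$curve$scale, tolerance = 1e-8)
  expect_equal(f2$curve$offset, 100 * f1$curve$offset, tolerance = 1e-8)
})

test_that("exact interpolation holds for random 3-point exponential series", {
  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, 0.5, 100); b <- runif(1, 0.02, 0.4)
    c0 <- runif(1, 0, 0.9 * a)
    t3 <- c(0, 7, 14)
    s <- group_series("g", t3, a * exp(b * t3) - c0, "uptake")
    f <- fit_exp(s)
    expect_equal(eval_curve(f$curve, t3), s$values, tolerance = 1e-8)
  }
})

test_that("rate recovery under 10% CV noise: median relative error < 10%", {
  # group means of n = 4 plants per time, multiplicative lognormal noise
  set.seed(101)
  s2 <- log(1 + 0.10^2)
  t3 <- c(0, 7, 14)
  truth <- 1.09 * exp(0.171 * t3) - 1.09
  err <- replicate(100, {
    means <- vapply(truth, function(m) {
      mean(m * rlnorm(4, -s2 / 2, sqrt(s2)))
    }, numeric(1))
    f <- fit_exp(group_series("g", t3, pmax(means, 1e-6), "uptake"))
    abs(f$curve$rate - 0.171) / 0.171
  })
  expect_lt(median(err), 0.10)
})

test_that("fit_group_pair composes fits and checks contracts", {
  t3 <- c(0, 7, 14)
  up <- group_series("tolerant", t3, 1.09 * exp(0.171 * t3) - 1.09, "uptake")
  rsa <- group_series("tolerant", t3, 110.2 * exp(0.082 * t3) - 22.2, "rsa")
  ec <- fit_group_pair(up, rsa)
  expect_s3_class(ec, "efficiency_curve")
  expect_equal(root_efficiency(ec, 0), 1.09 * 0.171 / 88.0,
               tolerance = 1e-6)
  rsa_other <- group_series("sensitive", t3,
                            108.1 * exp(0.045 * t3) - 37.4, "rsa")
  expect_error(fit_group_pair(up, rsa_other), "different groups")
  expect_error(fit_group_pair(rsa, rsa), "expected an uptake series")
})
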