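# Frozen expected values below were computed with the independent
# quadrature oracle in helper-oracles.R.

test_that("counterfactual uptake reproduces oracle quadrature", {
  gc <- ref_curves()
  cf7 <- counterfactual_uptake(gc$tolerant, gc$sensitive, 7)
  expect_equal(cf7$uptake, oracle$cf(oracle$RE_tol, oracle$RSA_sens, 7),
               tolerance = 1e-8)
  expect_equal(cf7$uptake, 1.765561, tolerance = 1e-6)
  expect_equal(round(cf7$uptake, 1), 1.8)
  expect_lt(cf7$quadrature_error, 1e-6 * cf7$uptake)
  # 28-DAT horizon: computed value, deviating from the narrated 6.7
  cf14 <- counterfactual_uptake(gc$tolerant, gc$sensitive, 14)
  expect_equal(cf14$uptake, 6.424276, tolerance = 1e-6)
  # empty interval
  expect_equal(counterfactual_uptake(gc$tolerant, gc$sensitive, 0)$uptake, 0)
  expect_error(counterfactual_uptake(gc$tolerant, gc$sensitive, -1),
               "non-negative")
})

test_that("self-consistency: own-pairing integral equals uptake increment", {
  gc <- ref_curves()
  expect_equal(counterfactual_uptake(gc$tolerant, gc$tolerant, 7)$uptake,
               eval_curve(gc$tolerant$uptake, 7) -
                 eval_curve(gc$tolerant$uptake, 0),
               tolerance = 1e-6)
  set.seed(13)
  for (i in 1:20) {
    g <- random_ec()
    t1 <- runif(1, 0.5, 14)
    expect_equal(counterfactual_uptake(g, g, t1)$uptake,
                 eval_curve(g$uptake, t1) - eval_curve(g$uptake, 0),
                 tolerance = 1e-6)
  }
})

test_that("attribution shares match oracle and sum to one exactly", {
  gc <- ref_curves()
  a7 <- decompose_difference(gc$tolerant, gc$sensitive, 7)
  # oracle on uptake increments (curves measure uptake since t = 0)
  inc <- function(f, t) f(t) - f(0)
  d7 <- inc(oracle$U_tol, 7) - inc(oracle$U_sens, 7)
  re7 <- (oracle$cf(oracle$RE_tol, oracle$RSA_sens, 7) -
            inc(oracle$U_sens, 7)) / d7
  rsa7 <- (oracle$cf(oracle$RE_sens, oracle$RSA_tol, 7) -
             inc(oracle$U_sens, 7)) / d7
  expect_equal(a7$re_share, re7, tolerance = 1e-8)
  expect_equal(a7$rsa_share, rsa7, tolerance = 1e-8)
  expect_equal(round(a7$re_share, 2), 0.43)
  expect_equal(round(a7$rsa_share, 2), 0.38)
  expect_equal(a7$re_share + a7$rsa_share + a7$interaction_share, 1,
               tolerance = 1e-9)
  a14 <- decompose_difference(gc$tolerant, gc$sensitive, 14)
  expect_equal(round(a14$re_share, 2), 0.29)
  expect_equal(a14$re_share + a14$rsa_share + a14$interaction_share, 1,
               tolerance = 1e-9)
  # identical groups: undefined attribution
  expect_error(decompose_difference(gc$tolerant, gc$tolerant, 7),
               "undefined")
})

test_that("counterfactual uptake is monotone in RE rate and RSA scale", {
  gc <- ref_curves()
  base <- counterfactual_uptake(gc$tolerant, gc$sensitive, 7)$uptake
  up_hot <- exp_curve(1.09, 0.20, 1.09, role = "uptake")
  hot <- efficiency_curve(up_hot, gc$tolerant$rsa, "hot")
  expect_gt(counterfactual_uptake(hot, gc$sensitive, 7)$uptake, base)
  rsa_big <- exp_curve(130, 0.045, 37.4, role = "rsa")
  big <- efficiency_curve(gc$sensitive$uptake, rsa_big, "big")
  expect_gt(counterfactual_uptake(gc$tolerant, big, 7)$uptake, base)
})

test_that("attribution_table reports one row per horizon", {
  gc <- ref_curves()
  tab <- attribution_table(gc$tolerant, gc$sensitive, horizons = c(7, 14))
  expect_equal(tab$dat, c(21, 28))
  expect_equal(tab$re_share + tab$rsa_share + tab$interaction_share,
               c(1, 1), tolerance = 1e-9)
})
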