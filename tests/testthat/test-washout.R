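# Washout-only comparators: biexponential and gamma-variate fits on the
# late window, their MRT formulas, and the comparison statistics.

biexp_tac <- function(A1 = 5e3, l1 = 0.05, A2 = 1e3, l2 = 0.002) {
  fr <- tac_frames()
  tm <- fr$t_start_min + fr$duration_min / 2
  tac(A1 * exp(-l1 * tm) + A2 * exp(-l2 * tm), fr)
}

test_that("biexponential MRT formula collapses correctly", {
  expect_equal(e2_mrt(A1 = 1, lam1 = 0.01, A2 = 0, lam2 = 1), 100)
  expect_equal(e2_mrt(A1 = 1, lam1 = 0.01, A2 = 1, lam2 = 0.01), 100)
  expect_equal(gv_mrt(0.5, 0.25), 2)
})

test_that("noiseless biexponential samples are recovered within 1 percent", {
  f <- fit_e2(biexp_tac(), window = c(5, 89), weighting = "ols")
  expect_false(f$failed)
  got <- unlist(f$params)
  expect_equal(got[["A1"]], 5e3, tolerance = 0.01)
  expect_equal(got[["lam1"]], 0.05, tolerance = 0.01)
  expect_equal(got[["A2"]], 1e3, tolerance = 0.01)
  expect_equal(got[["lam2"]], 0.002, tolerance = 0.01)
  expect_equal(f$mrt_wo, e2_mrt(5e3, 0.05, 1e3, 0.002), tolerance = 0.01)
  # inverse-square weighting recovers the same noiseless truth
  fw <- fit_e2(biexp_tac(), weighting = "inverse_square")
  expect_equal(fw$mrt_wo, f$mrt_wo, tolerance = 0.01)
  expect_equal(fw$model_id, "WLS_E2")
})

test_that("degenerate biexponentials fall back to a monoexponential", {
  fr <- tac_frames()
  tm <- fr$t_start_min + fr$duration_min / 2
  y <- tac(2e3 * exp(-0.01 * tm), fr)
  expect_warning(f <- fit_e2(y), "monoexponential")
  expect_equal(f$params$A2, 0)
  expect_equal(f$mrt_wo, 100, tolerance = 1e-4)
})

test_that("noiseless gamma-variate samples are recovered within 1 percent", {
  fr <- tac_frames()
  tm <- fr$t_start_min + fr$duration_min / 2
  y <- tac(1e3 * tm^(0.9 - 1) * exp(-0.003 * tm), fr)
  f <- fit_gv(y, method = "ols")
  expect_false(f$failed)
  expect_equal(f$params$alpha_w, 0.9, tolerance = 0.01)
  expect_equal(f$params$beta_w, 0.003, tolerance = 0.01)
  expect_equal(f$mrt_wo, 0.9 / 0.003, tolerance = 0.01)
})

test_that("zero regularization reproduces the unpenalized linearized fit", {
  y <- simulate_tac(reference_cases()[["2T"]], seed = 4)
  f0 <- fit_gv(y, method = "tk", lambda = 0)
  d <- gdctac:::window_frames(y, c(5, 89))
  cf <- lm(log(d$y) ~ log(d$t) + I(-d$t))$coefficients
  expect_equal(f0$params$alpha_w, unname(cf[2]) + 1, tolerance = 1e-8)
  expect_equal(f0$params$beta_w, unname(cf[3]), tolerance = 1e-8)
  # the adaptive scan returns a positive-rate fit with recorded lambda
  fs <- fit_gv(y, method = "tk")
  expect_false(fs$failed)
  expect_gt(fs$params$beta_w, 0)
  expect_true(is.finite(fs$params$lambda))
})

test_that("gamma-variate MRT equals the numerical moment of its density", {
  for (s in random_shapes(20, seed = 7)) {
    expect_equal(gv_mrt(s$alpha, s$beta),
                 mrt_numeric(function(t) gd_density(t, s$alpha, s$beta),
                             knots = c(1, 50)),
                 tolerance = 1e-6)
  }
})

test_that("interpolation CV follows the distance/interval definition", {
  same <- data.frame(mrt_L = rep(100, 3), mrt_R = rep(300, 3),
                     mrt_T = rep(200, 3))
  expect_equal(cv_interpolation(same), 0)
  two <- data.frame(mrt_L = c(100, 200), mrt_R = c(300, 400),
                    mrt_T = c(150, 350))
  expect_equal(cv_interpolation(two), 100 * sd(c(50, 150)) / 200,
               tolerance = 1e-10)
  expect_equal(cv_interpolation(two), 35.36, tolerance = 1e-3)
  atmin <- data.frame(mrt_L = c(100, 200), mrt_R = c(300, 400),
                      mrt_T = c(100, 200))
  expect_equal(cv_interpolation(atmin), 0)
  degen <- data.frame(mrt_L = 100, mrt_R = 100, mrt_T = 100)
  expect_error(cv_interpolation(rbind(degen, degen)), "undefined")
})

test_that("CV of RMSE against reference MRTs is as printed in its definition", {
  expect_equal(cv_rmse(c(200, 400), c(200, 400)), 0)
  expect_equal(cv_rmse(1.1 * c(200, 400), c(200, 400)),
               100 * sqrt(mean(c(20, 40)^2)) / 300)
  expect_equal(cv_rmse(1.1 * c(200, 400), c(200, 400)), 10.54,
               tolerance = 1e-3)
  expect_equal(cv_rmse(110, 100), 10)
  expect_error(cv_rmse(1:3, 1:4), "mismatch")
})
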