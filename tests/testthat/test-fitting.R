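# Poisson-loss fitting: loss function, arrival-time seeding, round-trip
# identifiability, determinism, and the reconstructed fit-error metrics.

test_that("Poisson loss is minimized at equality and matches closed values", {
  expect_equal(poisson_loss(2, 2), 2 - 2 * log(2), tolerance = 1e-12)
  expect_equal(poisson_loss(0, 3), 3)
  O <- c(5, 80, 1200, 40000)
  base <- poisson_loss(O, O)
  for (i in seq_along(O)) {
    for (eps in c(-0.02, 0.02)) {
      M <- O
      M[i] <- M[i] * (1 + eps)
      expect_gt(poisson_loss(O, M), base)
    }
  }
  expect_equal(poisson_loss(c(4, 9), c(2, 10), loss = "pearson_chi2"),
               (4 - 2)^2 / 2 + (9 - 10)^2 / 10)
  expect_error(poisson_loss(c(1, 2), c(1, 0)), "invalid model")
  expect_error(poisson_loss(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("arrival-time seeding lands inside the first frame near the truth", {
  y <- noiseless_tac("2L")  # generating t_A = 0.340
  est <- estimate_arrival_time(y)
  expect_gte(est, 0)
  expect_lt(est, 1)
  expect_lt(abs(est - 0.340), 0.3)
  # a TAC already at its peak in frame 1 seeds at zero
  y2 <- tac(c(100, 90, 80, 70, 60, 50))
  expect_warning(est2 <- estimate_arrival_time(y2), "decreases")
  expect_identical(est2, 0)
})

test_that("fit-error metrics follow the reconstructed definitions", {
  M <- c(100, 200, 300, 400, 500, 600, 700, 800)
  m0 <- fit_error_metrics(M, M)
  expect_equal(m0$fit_err_pct, 0)
  expect_equal(m0$one_minus_r2_pct, 0)
  expect_equal(m0$misregistration_pct, 0)
  O <- M + c(1, -2, 3, -1, 2, -3, 1, -1)
  m1 <- fit_error_metrics(O, M, n_params = 2)
  expect_equal(m1$corrected_fit_err_pct / m1$fit_err_pct, sqrt(8 / 6))
  expect_gte(m1$corrected_fit_err_pct, m1$fit_err_pct)
  # the clinical layout's 6-parameter correction factor
  M89 <- seq(10, 30, length.out = 89)
  m2 <- fit_error_metrics(M89 + rnorm(89), M89)
  expect_equal(m2$corrected_fit_err_pct / m2$fit_err_pct, sqrt(89 / 83),
               tolerance = 1e-10)
  expect_error(fit_error_metrics(1:5, 1:5), "more frames")
})

test_that("published per-case fit errors average 1.44 percent", {
  df <- reference_cases(as = "data.frame")
  expect_equal(mean(df$fit_err_pct), 1.44, tolerance = 0.005)
})

test_that("noiseless curves are refit to the generating parameters", {
  p <- reference_cases()[["2T"]]
  fit <- gdc_fit(noiseless_tac("2T"), control = gdc_control(n_restarts = 1))
  truth <- unlist(p[c("t_A", "a", "b", "alpha", "beta", "S")])
  expect_true(fit$converged)
  expect_lt(max(abs(coef(fit) / truth - 1)), 0.005)
  expect_lt(fit$metrics$fit_err_pct, 0.05)
})

test_that("fitting is deterministic given the TAC, control and seed", {
  y <- simulate_tac(small_params(), tac_frames(40), seed = 9)
  ctl <- gdc_control(n_restarts = 2, seed = 3, max_cycles = 6)
  f1 <- suppressWarnings(gdc_fit(y, control = ctl))
  f2 <- suppressWarnings(gdc_fit(y, control = ctl))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$loss_value, f2$loss_value)
})

test_that("additional polish cycles never worsen the loss", {
  y <- simulate_tac(small_params(), tac_frames(40), seed = 9)
  f1 <- suppressWarnings(gdc_fit(y, control = gdc_control(n_restarts = 1,
                                                          max_cycles = 1)))
  f3 <- suppressWarnings(gdc_fit(y, control = gdc_control(n_restarts = 1,
                                                          max_cycles = 5)))
  expect_lte(f3$loss_value, f1$loss_value)
})

test_that("degenerate TACs are rejected", {
  expect_error(gdc_fit(tac(rep(0, 20))), "no counts")
  expect_error(gdc_fit(tac(1:5)), "at least 10 frames")
})

test_that("fit methods expose fitted values, residuals, predictions and MRT", {
  y <- simulate_tac(small_params(), tac_frames(40), seed = 9)
  fit <- suppressWarnings(gdc_fit(y, control = gdc_control(n_restarts = 1)))
  expect_length(fitted(fit), 40)
  expect_equal(residuals(fit), y$counts - fitted(fit))
  rp <- residuals(fit, type = "pearson")
  expect_equal(rp, (y$counts - fitted(fit)) / sqrt(fitted(fit)))
  expect_equal(predict(fit), fitted(fit))
  d <- predict(fit, type = "density", times = c(-1, 0.5, 5))
  expect_identical(d[1], 0)
  expect_true(all(d >= 0))
  m <- mrt(fit)
  expect_equal(m$mrt_wo, fit$params$alpha / fit$params$beta)
  reps <- simulate(fit, nsim = 2, seed = 1)
  expect_length(reps, 2)
  expect_s3_class(reps[[1]], "tac")
  out <- utils::capture.output(print(summary(fit)))
  expect_true(any(grepl("MRT", out)))
})
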