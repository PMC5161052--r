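# Closed-form densities: gamma components, Bateman convolution, GDC with
# its confluent hypergeometric factor, and mean residence time calculus.

test_that("gamma density handles both branches and the origin", {
  expect_equal(gd_density(0, shape = 1, rate = 2), 2)
  expect_equal(gd_density(1, shape = 2, rate = 1), exp(-1))
  expect_equal(gd_density(-5, shape = 0.9, rate = 0.003), 0)
  expect_equal(gd_density(c(-1, 2, 7), 1.3, 0.5),
               c(0, dgamma(c(2, 7), 1.3, rate = 0.5)))
  # diverging origin for washout shapes is capped at 0 with a warning
  expect_warning(v <- gd_density(0, shape = 0.9, rate = 1), "diverges")
  expect_identical(v, 0)
  expect_error(gd_density(1, shape = -1, rate = 2), "positive")
  expect_error(gd_density(1, shape = 1, rate = 0), "positive")
})

test_that("Bateman convolution matches closed forms and is continuous at b = beta", {
  # b beta (e^-beta t - e^-b t)/(b - beta) at b=1, beta=0.5, t=1
  expect_equal(edc_density(1, b = 1, beta = 0.5), 0.2386512185411911,
               tolerance = 1e-12)
  expect_equal(edc_density(1, b = 1, beta = 1), exp(-1))
  expect_equal(edc_density(0, b = 3, beta = 0.2), 0)  # zero initial height
  expect_equal(edc_density(-2, b = 1, beta = 0.5), 0)
  # branch switch is continuous: limit formula vs general formula nearby
  t <- c(0.5, 2, 10)
  expect_equal(edc_density(t, 1, 1 + 1e-7), edc_density(t, 1, 1),
               tolerance = 1e-6)
  expect_error(edc_density(1, b = 0, beta = 1), "positive")
})

test_that("GDC density matches 50-digit reference values", {
  # frozen from mpmath hyp1f1 at 50 digits: b^a beta^alpha / Gamma(a+alpha)
  #   e^{-b tau} tau^{a+alpha-1} 1F1[alpha, a+alpha, (b-beta) tau]
  tau <- c(0.5, 1, 5, 30, 89, 500, 4400)
  ref_1L <- c(0.0022705732487459521, 0.0030339278374993739,
              0.0033254080904551889, 0.0024035438259647424,
              0.0018404714475593323, 0.00067249072816647703,
              3.6428648402920041e-7)
  expect_equal(gdc_density(tau, 0.846, 0.909, 0.8577, 0.001849), ref_1L,
               tolerance = 1e-10)
  ref_3L <- c(0.0012255570996639392, 0.0037884187265952632,
              0.0031229815947290908, 0.0024126853663678684,
              0.0018997497011544163, 0.00068411673290837517,
              1.9781768051613101e-7)
  expect_equal(gdc_density(tau, 7.878, 11.644, 0.8918, 0.002029), ref_3L,
               tolerance = 1e-10)
  # rate-reversed case (b < beta) exercises the Kummer transform branch
  ref_rev <- c(0.040250395837960678, 0.096413916139216557,
               0.11932547657516808, 3.0887207011351163e-6,
               1.4393856092107545e-18, 4.607518808880429e-107)
  expect_equal(gdc_density(tau[1:6], 2, 0.5, 0.8, 1.5), ref_rev,
               tolerance = 1e-10)
})

test_that("GDC reduces to the Bateman equation for a = alpha = 1", {
  tau <- seq(0.1, 100, by = 0.35)
  expect_equal(gdc_density(tau, 1, 1, 1, 0.5), edc_density(tau, 1, 0.5),
               tolerance = 1e-10)
  expect_equal(gdc_density(1, 1, 1, 1, 0.5), 0.2386512185411911,
               tolerance = 1e-10)
})

test_that("GDC reduces to a single gamma density for b = beta", {
  tau <- seq(0.1, 100, by = 0.35)
  expect_equal(gdc_density(tau, 1.5, 2, 0.5, 2), gd_density(tau, 2, 2),
               tolerance = 1e-10)
  expect_equal(gdc_density(1, 1.5, 2, 0.5, 2), 4 * exp(-2), tolerance = 1e-10)
})

test_that("GDC is zero at and before the origin, finite and non-negative far out", {
  for (p in reference_cases()) {
    expect_identical(gdc_density(c(-3, 0), p$a, p$b, p$alpha, p$beta), c(0, 0))
    tau <- c(seq(0.01, 89, length.out = 60), 10 * p$alpha / p$beta)
    v <- gdc_density(tau, p$a, p$b, p$alpha, p$beta)
    expect_true(all(is.finite(v)) && all(v >= 0))
  }
})

test_that("stable evaluation agrees with the naive printed formula where computable", {
  tau <- seq(0.2, 60, by = 0.4)  # (b - beta) tau stays below overflow
  for (p in reference_cases()[c("1R", "2T", "3L")]) {
    s <- gdc_density(tau, p$a, p$b, p$alpha, p$beta)
    nv <- gdc_density(tau, p$a, p$b, p$alpha, p$beta, method = "naive")
    expect_equal(nv, s, tolerance = 1e-10)
  }
})

test_that("compiled Kummer kernel matches the pure-R reference", {
  z <- c(0, 1e-8, 0.5, 10, 59.9, 60.1, 300, 5000)
  for (AB in list(c(0.8661, 4.5991), c(3, 3.9), c(0.2, 7))) {
    expect_equal(gdctac:::.kummer_log_m_cpp(AB[1], AB[2], z),
                 gdctac:::kummer_log_m(AB[1], AB[2], z), tolerance = 1e-12)
  }
})

test_that("washout tail of the GDC converges to the washout gamma density", {
  # at 500 min the delivery transient is long gone
  for (p in reference_cases()) {
    ratio <- gdc_density(500, p$a, p$b, p$alpha, p$beta) /
      gd_density(500, p$alpha, p$beta)
    expect_equal(ratio, 1, tolerance = 0.01)
  }
})

test_that("washout-shape gamma densities decrease monotonically", {
  tau <- seq(0.01, 400, length.out = 300)
  for (sh in c(0.3, 0.8577, 0.9408, 0.99)) {
    v <- gd_density(tau, sh, 0.004)
    expect_true(all(diff(v) < 0))
  }
})

test_that("MRT components and additivity follow the a/b + alpha/beta rule", {
  m <- gdc_mrt(a = 3.733, b = 5.211, alpha = 0.8661, beta = 0.004081,
               t_A = 0.334)
  expect_equal(m$mrt_fast, 0.716, tolerance = 1e-3)
  expect_equal(m$mrt_wo, 212.2, tolerance = 1e-3)
  expect_equal(m$mrt_total_from_injection, 0.334 + m$mrt_fast + m$mrt_wo)
  expect_equal(unlist(gdc_mrt(1, 1, 1, 1, 0)), c(mrt_fast = 1, mrt_wo = 1,
                                                 mrt_total_from_injection = 2))
  expect_error(gdc_mrt(1, 1, 1, 1, t_A = -0.1), "t_A")
})

test_that("numerical first moment matches closed forms", {
  expect_equal(mrt_numeric(function(t) dexp(t, 0.5)), 2, tolerance = 1e-7)
  expect_equal(mrt_numeric(function(t) gd_density(t, 0.8661, 0.004081),
                           knots = c(1, 50)),
               0.8661 / 0.004081, tolerance = 1e-6)
  expect_error(mrt_numeric(function(t) 2 * dexp(t, 1)), "not normalized")
})

test_that("numerical moment of the GDC equals the additive MRT (fixtures + random draws)", {
  for (p in reference_cases()[c("1L", "2T")]) {
    m <- mrt_numeric(function(t) gdc_density(t, p$a, p$b, p$alpha, p$beta),
                     knots = c(1, 5, 50))
    expect_equal(m, p$a / p$b + p$alpha / p$beta, tolerance = 1e-6)
  }
  for (s in random_shapes(100, seed = 42)) {
    m <- mrt_numeric(function(t) gdc_density(t, s$a, s$b, s$alpha, s$beta),
                     knots = c(1, 5, 50))
    expect_equal(m, s$a / s$b + s$alpha / s$beta, tolerance = 1e-6)
  }
})
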