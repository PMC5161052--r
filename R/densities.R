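#' Gamma density for delivery and washout phases
#'
#' Evaluates the gamma probability density
#' \deqn{f(\tau) = \frac{b^a}{\Gamma(a)} \tau^{a-1} e^{-b\tau}, \quad \tau \ge 0}
#' used both as the fast delivery component (shape \eqn{a}, rate \eqn{b}) and,
#' with shape \eqn{\alpha < 1}, as the monotonically decreasing washout
#' component of the GDC model.  Negative times return 0.
#'
#' For `shape < 1` the density diverges at the origin; evaluation at exactly
#' `tau = 0` returns 0 with a warning rather than `Inf`, because a framed
#' time-activity curve only ever integrates the density over an interval and
#' the integral is finite.
#'
#' @param tau Time in minutes; any real vector.
#' @param shape Dimensionless shape parameter, > 0.  Shape > 1 gives a skewed
#'   bell, shape < 1 a decaying spike (a valid washout).
#' @param rate Rate in 1/min, > 0.
#' @return Density values (per minute), same length as `tau`.
#' @seealso [gdc_density()], [edc_density()]
#' @examples
#' gd_density(1, shape = 2, rate = 1)   # e^-1
#' @export
gd_density <- function(tau, shape, rate) {
  check_positive(shape = shape, rate = rate)
  out <- numeric(length(tau))
  pos <- tau > 0
  out[pos] <- stats::dgamma(tau[pos], shape = shape, rate = rate)
  at0 <- !is.na(tau) & tau == 0
  if (any(at0)) {
    if (shape < 1) {
      warning("gamma density diverges at tau = 0 for shape < 1; returning 0")
      out[at0] <- 0
    } else {
      out[at0] <- stats::dgamma(0, shape = shape, rate = rate)
    }
  }
  out[is.na(tau)] <- NA_real_
  out
}

#' Exponential density convolution (Bateman equation)
#'
#' The convolution of two exponential densities with rates `b` and `beta`,
#' the classical parent/daughter activity curve:
#' \deqn{f(t) = b\beta \frac{e^{-\beta t} - e^{-b t}}{b - \beta}, \quad b \ne \beta}
#' with the removable singularity \eqn{b = \beta} evaluated as
#' \eqn{b^2 t e^{-bt}}.  Zero for \eqn{t < 0}; the initial height at
#' \eqn{t = 0} is zero.  This is the shape = 1 special case of the GDC.
#'
#' The limit formula is used whenever `|b - beta| < 1e-8 * b` so the branch
#' switch is continuous and free of catastrophic cancellation.
#'
#' @param t Time in minutes; any real vector.
#' @param b,beta Rates in 1/min, > 0.
#' @return Density values, same length as `t`.
#' @examples
#' edc_density(1, b = 1, beta = 0.5)
#' @export
edc_density <- function(t, b, beta) {
  check_positive(b = b, beta = beta)
  out <- numeric(length(t))
  pos <- !is.na(t) & t > 0
  if (abs(b - beta) < 1e-8 * b) {
    out[pos] <- b^2 * t[pos] * exp(-b * t[pos])
  } else {
    out[pos] <- b * beta * (exp(-beta * t[pos]) - exp(-b * t[pos])) / (b - beta)
  }
  out[is.na(t)] <- NA_real_
  out
}

#' Gamma distribution convolution (GDC) density
#'
#' Closed form of the convolution of a fast gamma density GD(a, b) with a
#' washout gamma density GD(alpha, beta):
#' \deqn{f(\tau) = \frac{b^a \beta^\alpha}{\Gamma(a+\alpha)} e^{-b\tau}
#'   \tau^{a+\alpha-1} \, {}_1F_1[\alpha, a+\alpha, (b-\beta)\tau], \quad \tau > 0}
#' and 0 for \eqn{\tau \le 0}.  For `a = alpha = 1` this reduces to the
#' Bateman equation ([edc_density()]); for `b = beta` it reduces to
#' `gd_density(tau, a + alpha, b)`.
#'
#' @details
#' The printed form multiplies a decaying exponential by a confluent
#' hypergeometric factor that grows like \eqn{e^{(b-\beta)\tau}}; evaluated
#' naively in floating point it overflows for clinical parameters well inside
#' the washout tail.  The default `"stable"` method therefore works in log
#' space and always evaluates the Kummer function at a positive argument
#' (using the Kummer transformation \eqn{M(A,B,-z) = e^{-z} M(B-A,B,z)} when
#' `b < beta`), where every series term is positive, so there is no
#' cancellation; a large-argument asymptotic expansion takes over for
#' arguments above 60.  The `"naive"` method evaluates the printed formula
#' directly and is retained only as a cross-check; it overflows for
#' `(b - beta) * tau` beyond roughly 700.
#'
#' @param tau Time since arrival, minutes; any real vector.
#' @param a,b Shape (dimensionless) and rate (1/min) of the fast component.
#' @param alpha,beta Shape and rate of the washout component; `alpha < 1`
#'   gives a monotone washout.
#' @param method `"stable"` (default) or `"naive"` (direct evaluation of the
#'   printed formula, for verification only).
#' @return Density values (per minute), same length as `tau`; finite and
#'   non-negative for all `tau` under the stable method.
#' @examples
#' gdc_density(1, a = 1, b = 1, alpha = 1, beta = 0.5)  # equals the Bateman form
#' @export
gdc_density <- function(tau, a, b, alpha, beta, method = c("stable", "naive")) {
  check_positive(a = a, b = b, alpha = alpha, beta = beta)
  method <- match.arg(method)
  out <- numeric(length(tau))
  pos <- !is.na(tau) & tau > 0
  if (any(pos)) {
    tp <- tau[pos]
    B <- a + alpha
    if (method == "naive") {
      pref <- b^a * beta^alpha / gamma(B)
      out[pos] <- pref * exp(-b * tp) * tp^(B - 1) *
        kummer_m_signed(alpha, B, (b - beta) * tp)
    } else {
      out[pos] <- .gdc_density_cpp(tp, a, b, alpha, beta)
    }
  }
  out[is.na(tau)] <- NA_real_
  out
}

# log M(A, B, z) for scalar A, B > 0 and vector z >= 0.
# Small z: ascending Kummer series, all terms positive, direct accumulation
# (M(A,B,60) ~ e^60, far below overflow).  Large z: asymptotic expansion
# M ~ Gamma(B)/Gamma(A) e^z z^(A-B) sum_n (B-A)_n (1-A)_n / (n! z^n),
# truncated at the smallest term; at z = 60 the smallest term is ~e^-60 so
# the two branches overlap to machine precision.
kummer_log_m <- function(A, B, z) {
  stopifnot(A > 0, B > 0, all(z >= -1e-300))
  out <- numeric(length(z))
  small <- z < 60
  if (any(small)) {
    zs <- z[small]
    s <- rep(1, length(zs))
    term <- rep(1, length(zs))
    for (n in 0:1000) {
      term <- term * (A + n) / (B + n) * zs / (n + 1)
      s <- s + term
      if (all(term <= 1e-17 * s)) break
    }
    out[small] <- log(s)
  }
  if (any(!small)) {
    zl <- z[!small]
    s <- rep(1, length(zl))
    term <- rep(1, length(zl))
    live <- rep(TRUE, length(zl))
    for (n in 0:60) {
      nxt <- term * (B - A + n) * (1 - A + n) / ((n + 1) * zl)
      # asymptotic series: stop (per element) once terms stop shrinking
      live <- live & abs(nxt) < abs(term) & abs(term) > 1e-17 * abs(s)
      if (!any(live)) break
      term[live] <- nxt[live]
      s[live] <- s[live] + nxt[live]
    }
    out[!small] <- lgamma(B) - lgamma(A) + zl + (A - B) * log(zl) + log(s)
  }
  out
}

# direct signed-argument Kummer series, no log protection: the "naive"
# printed-formula route.  Overflows for large positive z by design.
kummer_m_signed <- function(A, B, z) {
  s <- rep(1, length(z))
  term <- rep(1, length(z))
  for (n in 0:1000) {
    term <- term * (A + n) / (B + n) * z / (n + 1)
    s <- s + term
    if (all(abs(term) <= 1e-17 * abs(s), na.rm = TRUE)) break
  }
  s
}

#' Mean residence times of a GDC model
#'
#' The mean residence time of a density is its first moment,
#' \eqn{\int_0^\infty t f(t)\,dt}, and MRTs of convolved (summed) random
#' variables add.  For the arrival-offset GDC this gives
#' \eqn{t_A + a/b + \alpha/\beta}.  Tracer residence *within* the organ
#' starts at first arrival, so the reported organ components are
#' `mrt_fast = a/b` (delivery and uptake) and `mrt_wo = alpha/beta`
#' (washout); the arrival offset `t_A` contributes only to the
#' total-from-injection time.
#'
#' @param a,b,alpha,beta GDC shape parameters (see [gdc_density()]).
#' @param t_A Arrival time offset in minutes, >= 0.
#' @return A list with `mrt_fast`, `mrt_wo`, and `mrt_total_from_injection`,
#'   all in minutes.
#' @examples
#' gdc_mrt(a = 3.733, b = 5.211, alpha = 0.8661, beta = 0.004081)
#' @export
gdc_mrt <- function(a, b, alpha, beta, t_A = 0) {
  check_positive(a = a, b = b, alpha = alpha, beta = beta)
  if (t_A < 0) stop("t_A must be >= 0")
  list(
    mrt_fast = a / b,
    mrt_wo = alpha / beta,
    mrt_total_from_injection = t_A + a / b + alpha / beta
  )
}

#' First moment of a density by adaptive quadrature
#'
#' Numerical oracle for mean residence time: integrates \eqn{t f(t)} over
#' \eqn{[0, \infty)}.  The density's area is checked first and must be within
#' `area.tol` of 1.
#'
#' @param density A vectorized function of time (minutes) returning density
#'   values; must be integrable with unit area.
#' @param knots Optional interior break points passed to the quadrature to
#'   help it resolve multi-scale shapes (e.g. a sharp delivery peak plus a
#'   slow washout tail).
#' @param area.tol Maximum tolerated deviation of the density's area from 1.
#' @return The first moment in minutes.
#' @examples
#' mrt_numeric(function(t) dexp(t, rate = 0.5))  # 2
#' @export
mrt_numeric <- function(density, knots = NULL, area.tol = 1e-3) {
  pieces <- c(0, sort(knots), Inf)
  quad <- function(f) {
    sum(vapply(seq_len(length(pieces) - 1), function(i) {
      stats::integrate(f, pieces[i], pieces[i + 1],
                       rel.tol = 1e-10, abs.tol = 1e-9,
                       subdivisions = 500L)$value
    }, numeric(1)))
  }
  area <- quad(density)
  if (abs(area - 1) > area.tol) {
    stop(sprintf("density is not normalized: area = %.6g (tolerance %g)",
                 area, area.tol))
  }
  quad(function(t) t * density(t))
}

# shared positivity validator: stops with the offending name
check_positive <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("parameter '%s' must be a single positive finite number", nm))
    }
  }
  invisible(TRUE)
}
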