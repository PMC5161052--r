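#' Control settings for GDC fitting
#'
#' @param loss Loss function: `"poisson_nll"` (Poisson negative
#'   log-likelihood up to an observed-only constant; the default) or
#'   `"pearson_chi2"` (model-estimated variance weights).
#' @param stop_rel_tol Relative loss-difference stop condition between
#'   successive optimizer cycles.  The default 1e-20 is below double
#'   precision, so in practice the optimizer polishes until the simplex
#'   cannot improve the loss at all.
#' @param max_iter Maximum Nelder-Mead iterations per cycle.
#' @param max_cycles Maximum polish cycles (each cycle restarts the simplex
#'   at the current best point, the standard guard against premature
#'   simplex collapse).
#' @param n_restarts Number of jittered starting points; the best final loss
#'   wins.  There is no guarantee Nelder-Mead finds a global minimum, so
#'   interactive fits default to 5.
#' @param t_A_bounds Interval (minutes) constraining the arrival time; if
#'   `NULL`, `[0, end of first frame)` is used.
#' @param quadrature Frame-integration rule passed to [expected_counts()].
#' @param warn_alpha Warn when the fitted washout shape is >= 1 (not a valid
#'   monotone washout; treated as a finding, not a hard bound).
#' @param seed Integer seed controlling restart jitter (fits are
#'   deterministic given the TAC, the control, and this seed).
#' @return A list of class `"gdc_control"`.
#' @export
gdc_control <- function(loss = c("poisson_nll", "pearson_chi2"),
                        stop_rel_tol = 1e-20, max_iter = 3000L,
                        max_cycles = 40L, n_restarts = 5L,
                        t_A_bounds = NULL, quadrature = "gl3",
                        warn_alpha = TRUE, seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(stop_rel_tol > 0, max_iter >= 10, max_cycles >= 1,
            n_restarts >= 1)
  if (!is.null(t_A_bounds)) {
    stopifnot(length(t_A_bounds) == 2L, diff(t_A_bounds) > 0)
  }
  structure(list(loss = loss, stop_rel_tol = stop_rel_tol,
                 max_iter = as.integer(max_iter),
                 max_cycles = as.integer(max_cycles),
                 n_restarts = as.integer(n_restarts),
                 t_A_bounds = t_A_bounds, quadrature = quadrature,
                 warn_alpha = warn_alpha, seed = as.integer(seed)),
            class = "gdc_control")
}

#' Poisson loss between observed and expected framed counts
#'
#' The default is the Poisson negative log-likelihood dropped of its
#' observed-only constant, \eqn{\sum_i (M_i - O_i \log M_i)}, minimized at
#' \eqn{M = O}.  `"pearson_chi2"` gives \eqn{\sum_i (O_i - M_i)^2 / M_i}.
#'
#' @param observed Observed counts, >= 0.
#' @param expected Model expectations, > 0 wherever the observation is
#'   positive.
#' @param loss `"poisson_nll"` or `"pearson_chi2"`.
#' @return Scalar loss.
#' @examples
#' poisson_loss(2, 2)  # 2 - 2 log 2
#' @export
poisson_loss <- function(observed, expected,
                         loss = c("poisson_nll", "pearson_chi2")) {
  loss <- match.arg(loss)
  if (length(observed) != length(expected)) stop("length mismatch")
  if (any(observed < 0)) stop("observed counts must be non-negative")
  if (any(expected <= 0)) stop("invalid model: non-positive expected counts")
  if (loss == "poisson_nll") {
    o <- observed > 0
    sum(expected) - sum(observed[o] * log(expected[o]))
  } else {
    sum((observed - expected)^2 / expected)
  }
}

#' Initial arrival-time estimate from the rising limb
#'
#' Reconstructs the tracer arrival time `t_A` from the fraction of the
#' early plateau captured by the first frame.  The counting rate is modelled
#' as growing linearly from zero at `t_A` through the first frame and
#' reaching the early maximum within the second, so the ratio of first-frame
#' counts to the early peak-rate counts,
#' \eqn{\rho = C_1 / C_{peak}}, satisfies
#' \eqn{u^2 / ((u+d)^2 - u^2) = \rho} with \eqn{u} the covered part of
#' frame 1 and \eqn{d} the second-frame duration, giving the closed form
#' \eqn{u = d(\rho + \sqrt{\rho^2 + \rho})} and \eqn{t_A = t_1^{end} - u},
#' clipped to `[0, end of first frame)`.  A TAC that decreases from the
#' first frame (first frame already at peak) returns 0 with a warning.
#' This only seeds the optimizer; `t_A` remains a free fitted parameter.
#'
#' @param x A `"tac"` object with at least 5 frames.
#' @return Arrival-time estimate in minutes.
#' @export
estimate_arrival_time <- function(x) {
  stopifnot(inherits(x, "tac"))
  if (nrow(x) < 5L) stop("need at least 5 frames")
  h1 <- x$t_start_min[1L] + x$duration_min[1L]
  rate <- x$counts / x$duration_min
  if (rate[2L] <= rate[1L]) {
    warning("TAC decreases from the first frame; using t_A = 0")
    return(0)
  }
  # early peak rate: frames 2..5 up to the global peak
  k <- min(max(which.max(rate), 2L), 5L)
  d <- x$duration_min[2L]
  rho <- x$counts[1L] / (max(rate[2:k]) * d)
  u <- d * (rho + sqrt(rho^2 + rho))
  min(max(h1 - u, 0), h1 * (1 - 1e-9))
}

# parameter transform: unconstrained theta <-> constrained params
theta_to_params <- function(theta, bounds, case = NULL) {
  t_A <- bounds[1L] + diff(bounds) * stats::plogis(theta[1L])
  gdc_params(t_A = t_A, a = exp(theta[2L]), b = exp(theta[3L]),
             alpha = exp(theta[4L]), beta = exp(theta[5L]),
             S = exp(theta[6L]), case = case)
}

params_to_theta <- function(p, bounds) {
  f <- (p$t_A - bounds[1L]) / diff(bounds)
  f <- min(max(f, 1e-6), 1 - 1e-6)
  c(stats::qlogis(f), log(p$a), log(p$b), log(p$alpha), log(p$beta), log(p$S))
}

# data-driven starting values: scale from total counts, washout rate from
# the log-linear tail slope, fast component from the peak position
initial_params <- function(x, decay) {
  t_A0 <- suppressWarnings(estimate_arrival_time(x))
  tm <- x$t_start_min + x$duration_min / 2
  rate <- x$counts / x$duration_min
  S0 <- sum(x$counts)
  if (decay$enabled) S0 <- S0 / mean(decay_factor(tm, decay))
  alpha0 <- 0.9
  tail_i <- which(tm >= stats::median(tm) & rate > 0)
  lam <- 1 / max(tm)
  if (length(tail_i) >= 3L) {
    y <- log(rate[tail_i])
    if (decay$enabled) y <- y + log(2) * tm[tail_i] / decay$half_life
    sl <- unname(stats::lm.fit(cbind(1, tm[tail_i]), y)$coefficients[2L])
    if (is.finite(sl) && sl < 0) lam <- -sl
  }
  beta0 <- alpha0 * lam
  a0 <- 1.5
  t_peak <- tm[which.max(rate)]
  b0 <- a0 / max(t_peak - t_A0, 0.5)
  gdc_params(t_A = t_A0, a = a0, b = b0, alpha = alpha0, beta = beta0,
             S = max(S0, 1))
}

#' Fit the GDC model to a time-activity curve
#'
#' Estimates the six GDC parameters (`t_A`, `a`, `b`, `alpha`, `beta`, `S`)
#' from framed ROI counts by minimizing a Poisson loss between observed and
#' expected counts, using Nelder-Mead on log-transformed shape/rate/scale
#' parameters (a bounded logistic transform for `t_A`).  When `decay` is
#' enabled the expectation includes the physical decay factor, so raw
#' (non-decay-corrected) counts can be fitted and decay-corrected kinetics
#' read from the parameters ("decay-simulated" fitting).
#'
#' Each starting point (one data-driven start plus `n_restarts - 1` jittered
#' copies) is polished by repeated Nelder-Mead cycles until the loss stops
#' improving (relative change below `stop_rel_tol`) or `max_cycles` is
#' reached; the best final loss wins.  The fit is deterministic given the
#' TAC, the control settings, and the control seed.
#'
#' @param x A `"tac"` object with at least 10 frames and positive total
#'   counts.
#' @param decay A [decay_config()].
#' @param control A [gdc_control()].
#' @param start Optional [gdc_params()] starting values overriding the
#'   data-driven initialization.
#' @return An object of class `"gdc_fit"` with components `params`
#'   ([gdc_params()]), `loss_value`, `metrics` (see [fit_error_metrics()]),
#'   `converged`, `n_evaluations`, and supporting data; methods include
#'   [coef()], [fitted()], [residuals()], [predict()], [simulate()],
#'   [summary()] and [plot()].
#' @examples
#' \donttest{
#' p <- reference_cases()[["1R"]]
#' y <- simulate_tac(p, seed = 1)
#' fit <- gdc_fit(y, control = gdc_control(n_restarts = 1))
#' coef(fit)
#' mrt(fit)
#' }
#' @export
gdc_fit <- function(x, decay = decay_config(), control = gdc_control(),
                    start = NULL) {
  stopifnot(inherits(x, "tac"), inherits(control, "gdc_control"))
  if (nrow(x) < 10L) stop("need at least 10 frames")
  if (sum(x$counts) <= 0) stop("invalid input: TAC has no counts")
  bounds <- control$t_A_bounds
  if (is.null(bounds)) bounds <- c(0, x$t_start_min[1L] + x$duration_min[1L])
  frames <- x[c("frame", "t_start_min", "duration_min")]
  obs <- x$counts
  nev <- 0L
  # the optimizer minimizes the Poisson deviance (NLL relative to the
  # saturated model) rather than the raw NLL: the two differ by an
  # observed-only constant, so the minimizer is identical, but the
  # deviance is ~O(n) instead of ~O(total counts) and its floating-point
  # rounding no longer drowns the shallow delivery-phase ridge
  objective <- function(theta) {
    nev <<- nev + 1L
    p <- theta_to_params(theta, bounds)
    M <- expected_counts(p, frames, decay, quadrature = control$quadrature)
    if (any(M <= 0 & obs > 0) || any(!is.finite(M))) return(1e300)
    if (control$loss == "poisson_nll") {
      # per-frame deviance terms M - O - O log1p((M - O)/O) are each >= 0,
      # so the sum has no cancellation and stays resolvable to ~1e-15
      # even when the fit is essentially exact
      o <- obs > 0
      sum(M[!o]) +
        sum(M[o] - obs[o] - obs[o] * log1p((M[o] - obs[o]) / obs[o]))
    } else {
      poisson_loss(obs, pmax(M, 1e-300), control$loss)
    }
  }
  p0 <- if (is.null(start)) initial_params(x, decay) else start
  theta0 <- params_to_theta(p0, bounds)
  starts <- list(theta0)
  if (control$n_restarts > 1L) {
    jit <- with_seed(control$seed, lapply(seq_len(control$n_restarts - 1L),
      function(i) theta0 + stats::rnorm(6L, sd = 0.15)))
    starts <- c(starts, jit)
  }
  best <- NULL
  for (th in starts) {
    res <- nm_polish(objective, th, control)
    if (is.null(best) || res$value < best$value) best <- res
  }
  params <- theta_to_params(best$par, bounds, case = NULL)
  if (control$warn_alpha && params$alpha >= 1) {
    warning(sprintf("fitted washout shape alpha = %.3f >= 1 (not a monotone washout)",
                    params$alpha))
  }
  M <- expected_counts(params, frames, decay, quadrature = control$quadrature)
  metrics <- fit_error_metrics(obs, M)
  loss_value <- poisson_loss(obs, pmax(M, 1e-300), control$loss)
  structure(list(params = params, loss_value = loss_value,
                 deviance = if (control$loss == "poisson_nll") best$value,
                 metrics = metrics, converged = best$converged,
                 n_evaluations = nev, tac = x, decay = decay,
                 control = control, fitted_counts = M),
            class = "gdc_fit")
}

# repeated Nelder-Mead with simplex restarts at the incumbent optimum,
# each followed by a quasi-Newton refinement: the simplex handles the
# globally rough surface, BFGS tracks the narrow curved valley of the
# delivery-phase ridge that collapses a simplex prematurely
nm_polish <- function(fn, theta, control) {
  f_prev <- fn(theta)
  converged <- FALSE
  for (cycle in seq_len(control$max_cycles)) {
    opt <- stats::optim(theta, fn, method = "Nelder-Mead",
                        control = list(maxit = control$max_iter,
                                       reltol = max(control$stop_rel_tol,
                                                    1e-15)))
    ref <- tryCatch(
      stats::optim(opt$par, fn, method = "BFGS",
                   control = list(maxit = 150, reltol = 1e-15,
                                  ndeps = rep(1e-7, length(theta)))),
      error = function(e) opt)
    if (ref$value <= opt$value) opt <- ref
    theta <- opt$par
    drop <- f_prev - opt$value
    # the relative stop condition is far below double precision; an
    # absolute floor just above the resolution of the cancellation-free
    # deviance ends the polish once neither optimizer can improve it
    if (drop <= max(control$stop_rel_tol * abs(opt$value), 1e-11)) {
      converged <- TRUE
      f_prev <- min(f_prev, opt$value)
      break
    }
    f_prev <- opt$value
  }
  list(par = theta, value = f_prev, converged = converged)
}

#' Goodness-of-fit metrics for a framed-count model
#'
#' Computes the fit-quality summaries reported alongside GDC fits.  These
#' are documented reconstructions:
#' \itemize{
#'   \item `fit_err_pct`: 100 x RMS(O - M) / mean(O);
#'   \item `corrected_fit_err_pct`: the fit error inflated by
#'     \eqn{\sqrt{n/(n-p)}} to offset the use of `n_params` fitted
#'     parameters;
#'   \item `noise_pct`: the RMS relative Poisson standard deviation per
#'     frame, 100 x sqrt(mean(1/M));
#'   \item `misregistration_pct`: the quadrature residual
#'     \eqn{\sqrt{\max(corrected^2 - noise^2, 0)}}, i.e. systematic
#'     model-data discrepancy beyond counting noise;
#'   \item `one_minus_r2_pct`: 100 x (1 - Pearson(O, M)^2).
#' }
#'
#' @param observed,fitted Equal-length positive count vectors.
#' @param n_params Number of fitted parameters (default 6).
#' @return Named list of the five percentages.
#' @export
fit_error_metrics <- function(observed, fitted, n_params = 6L) {
  n <- length(observed)
  if (length(fitted) != n) stop("length mismatch")
  if (n <= n_params) stop("need more frames than fitted parameters")
  fit_err <- 100 * sqrt(mean((observed - fitted)^2)) / mean(observed)
  corrected <- fit_err * sqrt(n / (n - n_params))
  noise <- 100 * sqrt(mean(1 / fitted))
  misreg <- sqrt(max(corrected^2 - noise^2, 0))
  r <- stats::cor(observed, fitted)
  list(fit_err_pct = fit_err, corrected_fit_err_pct = corrected,
       noise_pct = noise, misregistration_pct = misreg,
       one_minus_r2_pct = 100 * (1 - r^2))
}

#' @export
coef.gdc_fit <- function(object, ...) {
  unlist(object$params[c("t_A", "a", "b", "alpha", "beta", "S")])
}

#' @rdname mrt
#' @export
mrt.gdc_fit <- function(object, ...) mrt(object$params)

#' @export
fitted.gdc_fit <- function(object, ...) object$fitted_counts

#' @export
residuals.gdc_fit <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$tac$counts - object$fitted_counts
  if (type == "pearson") r <- r / sqrt(object$fitted_counts)
  r
}

#' Predict expected counts or model density from a GDC fit
#'
#' @param object A `"gdc_fit"`.
#' @param newdata Frame layout (as [tac_frames()]); defaults to the fitted
#'   frames.  Ignored for `type = "density"`.
#' @param type `"counts"` for expected framed counts, `"density"` for the
#'   fitted scaled density `S * f(t - t_A)` (optionally decayed) at `times`.
#' @param times Evaluation times (minutes) for `type = "density"`.
#' @param decay Decay configuration; defaults to the one used in the fit.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.gdc_fit <- function(object, newdata = NULL,
                            type = c("counts", "density"), times = NULL,
                            decay = object$decay, ...) {
  type <- match.arg(type)
  p <- object$params
  if (type == "counts") {
    if (is.null(newdata)) {
      newdata <- object$tac[c("frame", "t_start_min", "duration_min")]
    }
    return(expected_counts(p, newdata, decay,
                           quadrature = object$control$quadrature))
  }
  if (is.null(times)) {
    times <- seq(0, max(object$tac$t_start_min + object$tac$duration_min),
                 length.out = 400L)
  }
  p$S * gdc_density(times - p$t_A, p$a, p$b, p$alpha, p$beta) *
    decay_factor(times, decay)
}

#' Simulate Poisson replicate TACs from a fitted GDC model
#'
#' @param object A `"gdc_fit"`.
#' @param nsim Number of replicate curves.
#' @param seed Optional integer seed (the caller's RNG state is restored).
#' @param ... Unused.
#' @return A list of `"tac"` objects of length `nsim`.
#' @export
simulate.gdc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  frames <- object$tac[c("frame", "t_start_min", "duration_min")]
  seeds <- derive_seeds(seed, nsim)
  lapply(seq_len(nsim), function(i) {
    simulate_tac(object$params, frames, object$decay, seed = seeds[i])
  })
}

#' @export
print.gdc_fit <- function(x, ...) {
  cat("GDC model fit (", x$control$loss, " loss",
      if (x$decay$enabled) ", decay-simulated" else "", ")\n", sep = "")
  print(signif(coef(x), 5))
  m <- mrt(x)
  cat(sprintf("MRT fast %.3f min, MRT washout %.1f min\n",
              m$mrt_fast, m$mrt_wo))
  cat(sprintf("fit error %.3f%% (corrected %.3f%%), noise %.3f%%, 1-R2 %.3f%%\n",
              x$metrics$fit_err_pct, x$metrics$corrected_fit_err_pct,
              x$metrics$noise_pct, x$metrics$one_minus_r2_pct))
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
summary.gdc_fit <- function(object, ...) {
  out <- list(coef = coef(object), mrt = mrt(object),
              metrics = object$metrics, loss = object$loss_value,
              converged = object$converged,
              n_evaluations = object$n_evaluations,
              n_frames = nrow(object$tac), decay = object$decay)
  class(out) <- "summary.gdc_fit"
  out
}

#' @export
print.summary.gdc_fit <- function(x, ...) {
  cat("GDC model fit summary\n")
  cat(sprintf("  frames: %d   loss: %.6g   evaluations: %d   converged: %s\n",
              x$n_frames, x$loss, x$n_evaluations, x$converged))
  cat("  parameters:\n")
  print(signif(x$coef, 6))
  cat(sprintf("  MRT: fast %.3f min, washout %.1f min, total from injection %.1f min\n",
              x$mrt$mrt_fast, x$mrt$mrt_wo, x$mrt$mrt_total_from_injection))
  with(x$metrics, cat(sprintf(
    "  fit err %.3f%%  corrected %.3f%%  noise %.3f%%  misregistration %.3f%%  1-R2 %.3f%%\n",
    fit_err_pct, corrected_fit_err_pct, noise_pct, misregistration_pct,
    one_minus_r2_pct)))
  invisible(x)
}

#' @export
plot.gdc_fit <- function(x, log = "", ...) {
  tm <- x$tac$t_start_min + x$tac$duration_min / 2
  graphics::plot(tm, x$tac$counts, log = log,
                 xlab = "time from injection (min)",
                 ylab = "counts per frame",
                 main = "Time-activity curve and GDC fit", ...)
  graphics::lines(tm, x$fitted_counts, col = "red", lwd = 2)
  invisible(x)
}
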