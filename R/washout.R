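# Washout-only comparator models: biexponential (E2) and gamma variate (GV),
# fit on a late window after the activity peak.  These are maximal at their
# start and ignore delivery, so they are fit only from the 5th minute on by
# default and serve as comparators for the full GDC concentration model.

# frames whose end time falls inside [window[1], window[2]]; for the
# clinical 1-min layout and window c(5, 89) this selects frames 5..89
window_frames <- function(x, window) {
  t_end <- x$t_start_min + x$duration_min
  keep <- t_end >= window[1L] - 1e-9 & t_end <= window[2L] + 1e-9
  if (sum(keep) < 6L) stop("need at least 6 frames inside the fitting window")
  tm <- x$t_start_min[keep] + x$duration_min[keep] / 2
  list(t = tm, y = x$counts[keep] / x$duration_min[keep])
}

new_washout_fit <- function(model_id, params, mrt_wo, window,
                            failed = FALSE, note = NULL) {
  structure(list(model_id = model_id, params = params, mrt_wo = mrt_wo,
                 window = window, failed = failed, note = note),
            class = "washout_fit")
}

#' @export
print.washout_fit <- function(x, ...) {
  cat(sprintf("Washout model %s, window [%g, %g] min\n",
              x$model_id, x$window[1L], x$window[2L]))
  print(signif(unlist(x$params), 5))
  cat(sprintf("MRT washout: %.1f min%s\n", x$mrt_wo,
              if (x$failed) "  [FAILED FIT]" else ""))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Mean residence time of a biexponential washout
#'
#' For \eqn{A_1 e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t}} the normalized
#' first moment is
#' \eqn{(A_1/\lambda_1^2 + A_2/\lambda_2^2) / (A_1/\lambda_1 + A_2/\lambda_2)}.
#'
#' @param A1,A2 Amplitudes >= 0 (at least one positive).
#' @param lam1,lam2 Rates > 0 (1/min).
#' @return MRT in minutes.
#' @examples
#' e2_mrt(A1 = 1, lam1 = 0.01, A2 = 0, lam2 = 1)  # 100
#' @export
e2_mrt <- function(A1, lam1, A2, lam2) {
  stopifnot(A1 >= 0, A2 >= 0, A1 + A2 > 0, lam1 > 0, lam2 > 0)
  (A1 / lam1^2 + A2 / lam2^2) / (A1 / lam1 + A2 / lam2)
}

#' Mean residence time of a gamma-variate washout
#'
#' The gamma variate \eqn{K t^{\alpha-1} e^{-\beta t}} is a scaled gamma
#' density, so its MRT is \eqn{\alpha/\beta}.
#'
#' @param alpha Shape > 0.
#' @param beta Rate > 0 (1/min).
#' @return MRT in minutes.
#' @examples
#' gv_mrt(0.5, 0.25)  # 2
#' @export
gv_mrt <- function(alpha, beta) {
  check_positive(alpha = alpha, beta = beta)
  alpha / beta
}

#' Fit a biexponential washout model
#'
#' Least-squares fit of \eqn{A_1 e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t}} to
#' the counts in a late fitting window, with unit weights (`"ols"`) or
#' \eqn{1/C(t)^2} weights (`"inverse_square"`, which emphasizes the late
#' tail).  Starting values come from log-linear curve stripping (tail
#' peel-off).  If the two rates collapse onto each other the fit falls back
#' to a monoexponential with a warning.
#'
#' @param x A `"tac"` object.  Counts are assumed decay-corrected; pass
#'   `decay` to correct raw counts first.
#' @param window Fitting window in minutes (frames whose end time falls
#'   inside it); default `c(5, 89)`, i.e. the 5th through 89th minute.
#' @param weighting `"ols"` or `"inverse_square"`.
#' @param decay Optional enabled [decay_config()]: divide raw counts by the
#'   decay factor before fitting.
#' @return A `"washout_fit"` with the amplitudes/rates (ordered
#'   `lam1 >= lam2`) and `mrt_wo`.
#' @export
fit_e2 <- function(x, window = c(5, 89),
                   weighting = c("ols", "inverse_square"), decay = NULL) {
  stopifnot(inherits(x, "tac"))
  weighting <- match.arg(weighting)
  d <- window_frames(x, window)
  if (!is.null(decay) && decay$enabled) d$y <- d$y / decay_factor(d$t, decay)
  if (any(d$y <= 0)) stop("washout fitting requires positive counts in the window")
  w <- if (weighting == "ols") rep(1, length(d$y)) else 1 / d$y^2
  # curve stripping: slow component from the tail third, fast from the rest
  tail_i <- d$t >= stats::quantile(d$t, 2 / 3)
  cf2 <- stats::lm.fit(cbind(1, d$t[tail_i]), log(d$y[tail_i]))$coefficients
  lam2 <- unname(max(-cf2[2L], 1e-5))
  A2 <- unname(exp(cf2[1L]))
  resid <- d$y - A2 * exp(-lam2 * d$t)
  early <- !tail_i & resid > 0
  if (sum(early) >= 2L) {
    cf1 <- stats::lm.fit(cbind(1, d$t[early]), log(resid[early]))$coefficients
    lam1 <- unname(max(-cf1[2L], lam2 * 2))
    A1 <- unname(exp(cf1[1L]))
  } else {
    lam1 <- lam2 * 5
    A1 <- A2 / 10
  }
  dat <- data.frame(t = d$t, y = d$y)
  # overlapping components defeat single-pass stripping, so try a small
  # family of rate-pair starts and keep the best weighted RSS
  starts <- list(
    list(A1 = A1, l1 = lam1, A2 = A2, l2 = lam2),
    list(A1 = max(d$y) / 2, l1 = 0.1, A2 = A2, l2 = lam2 / 4),
    list(A1 = max(d$y), l1 = 0.05, A2 = A2 / 2, l2 = 0.002),
    list(A1 = A2 / 5, l1 = lam2 * 10, A2 = A2, l2 = lam2 / 2))
  fit <- NULL
  for (s0 in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(y ~ A1 * exp(-l1 * t) + A2 * exp(-l2 * t),
                        data = dat, start = s0, weights = w,
                        lower = c(0, 1e-8, 0, 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f) &&
        (is.null(fit) || stats::deviance(f) < stats::deviance(fit))) {
      fit <- f
    }
  }
  degenerate <- is.null(fit)
  if (!degenerate) {
    cf <- stats::coef(fit)
    ok <- all(is.finite(cf)) &&
      abs(cf["l1"] - cf["l2"]) >= 1e-4 * max(cf["l1"], cf["l2"]) &&
      cf["A1"] + cf["A2"] > 0 &&
      min(cf["A1"], cf["A2"]) > 1e-6 * (cf["A1"] + cf["A2"])
    degenerate <- !isTRUE(ok)
  }
  if (degenerate) {
    warning("biexponential fit degenerate; falling back to a monoexponential")
    fit <- minpack.lm::nlsLM(y ~ A * exp(-l * t), data = dat,
                             start = list(A = A2, l = lam2), weights = w,
                             lower = c(0, 1e-8))
    cf <- stats::coef(fit)
    params <- list(A1 = unname(cf["A"]), lam1 = unname(cf["l"]),
                   A2 = 0, lam2 = unname(cf["l"]))
    return(new_washout_fit(
      if (weighting == "ols") "OLS_E2" else "WLS_E2", params,
      1 / params$lam1, window, note = "monoexponential fallback"))
  }
  cf <- stats::coef(fit)
  if (cf["l1"] < cf["l2"]) cf <- cf[c("A2", "l2", "A1", "l1")]
  params <- list(A1 = unname(cf[1L]), lam1 = unname(cf[2L]),
                 A2 = unname(cf[3L]), lam2 = unname(cf[4L]))
  params$A1 <- max(params$A1, 0)
  params$A2 <- max(params$A2, 0)
  new_washout_fit(if (weighting == "ols") "OLS_E2" else "WLS_E2", params,
                  e2_mrt(params$A1, params$lam1, params$A2, params$lam2),
                  window)
}

#' Fit a gamma-variate washout model
#'
#' Fits \eqn{K t^{\alpha-1} e^{-\beta t}} to the counts in a late window.
#' `method = "ols"` is a nonlinear least-squares fit started from the
#' log-linearized model.  `method = "tk"` is a Tikhonov-regularized fit of
#' the linearized model
#' \eqn{\log C = \log K + (\alpha-1)\log t - \beta t}: a ridge penalty
#' `lambda` on the (standardized) slope coefficients is scanned
#' log-uniformly over 1e-6..1e2 (60 points) and the value minimizing the
#' estimated relative standard error of \eqn{\hat\beta} is kept — the
#' adaptive "least relative error of beta" selection rule.  This linearized
#' ridge scheme is a documented approximation to the original adaptive
#' Tikhonov gamma-variate algorithm, whose exact formulation is not
#' reproduced here.
#'
#' @inheritParams fit_e2
#' @param method `"ols"` or `"tk"`.
#' @param lambda For `method = "tk"`: a fixed ridge strength, or `NULL`
#'   (default) to select it by the minimum-relative-error-of-beta scan.
#'   `lambda = 0` reproduces the unpenalized linearized fit.
#' @return A `"washout_fit"` with `K`, `alpha_w`, `beta_w`, `mrt_wo`
#'   (`= alpha_w / beta_w`), and for `"tk"` the selected `lambda`.  A
#'   non-positive fitted rate sets `failed = TRUE`.
#' @export
fit_gv <- function(x, window = c(5, 89), method = c("ols", "tk"),
                   decay = NULL, lambda = NULL) {
  stopifnot(inherits(x, "tac"))
  method <- match.arg(method)
  d <- window_frames(x, window)
  if (!is.null(decay) && decay$enabled) d$y <- d$y / decay_factor(d$t, decay)
  if (any(d$y <= 0)) stop("washout fitting requires positive counts in the window")
  X <- cbind(1, log(d$t), -d$t)
  ylog <- log(d$y)
  cf0 <- stats::lm.fit(X, ylog)$coefficients
  if (method == "ols") {
    dat <- data.frame(t = d$t, y = d$y)
    start <- list(K = unname(exp(cf0[1L])), al = unname(max(cf0[2L] + 1, 0.05)),
                  be = unname(max(cf0[3L], 1e-5)))
    fit <- minpack.lm::nlsLM(y ~ K * t^(al - 1) * exp(-be * t), data = dat,
                             start = start,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    params <- list(K = unname(cf["K"]), alpha_w = unname(cf["al"]),
                   beta_w = unname(cf["be"]))
    failed <- params$beta_w <= 0 || params$alpha_w <= 0
    return(new_washout_fit("OLS_GV", params,
                           if (failed) NA_real_ else
                             gv_mrt(params$alpha_w, params$beta_w),
                           window, failed = failed))
  }
  # Tikhonov ridge on the standardized linearized design (intercept free)
  n <- nrow(X)
  mu <- colMeans(X[, 2:3])
  sdev <- apply(X[, 2:3], 2, stats::sd)
  Z <- cbind(1, sweep(sweep(X[, 2:3], 2, mu), 2, sdev, "/"))
  D <- diag(c(0, 1, 1))
  ridge_fit <- function(lam) {
    G <- crossprod(Z) / n + lam * D
    Ginv <- solve(G)
    A <- Ginv %*% t(Z) / n
    cz <- drop(A %*% ylog)
    H <- Z %*% A
    res <- ylog - drop(Z %*% cz)
    edf <- sum(diag(H))
    sigma2 <- sum(res^2) / max(n - edf, 1)
    covz <- sigma2 * tcrossprod(A)
    # back-transform the -t coefficient: beta = cz[3] / sd(-t column)
    beta_hat <- cz[3L] / sdev[2L]
    se_beta <- sqrt(covz[3L, 3L]) / sdev[2L]
    alpha_hat <- cz[2L] / sdev[1L] + 1
    lnK <- cz[1L] - sum(cz[2:3] * mu / sdev)
    list(beta = beta_hat, se = se_beta, alpha = alpha_hat, lnK = lnK)
  }
  if (is.null(lambda)) {
    grid <- 10^seq(-6, 2, length.out = 60)
    fits <- lapply(grid, ridge_fit)
    rel <- vapply(fits, function(f) {
      if (!is.finite(f$beta) || f$beta <= 0) Inf else f$se / f$beta
    }, numeric(1))
    k <- which.min(rel)
    best <- fits[[k]]
    lambda <- grid[k]
  } else {
    best <- ridge_fit(lambda)
  }
  params <- list(K = exp(best$lnK), alpha_w = best$alpha, beta_w = best$beta,
                 lambda = lambda)
  failed <- !is.finite(best$beta) || best$beta <= 0 || best$alpha <= 0
  new_washout_fit("TK_GV", params,
                  if (failed) NA_real_ else gv_mrt(best$alpha, best$beta),
                  window, failed = failed)
}

#' Interpolation quality of total-organ MRTs
#'
#' For each patient with left-lobe, right-lobe and total-organ MRT values,
#' the distance to interpolation is \eqn{d = MRT_T - \min(MRT_L, MRT_R)}
#' and the interpolation interval is \eqn{ii = |MRT_L - MRT_R|}.  The
#' coefficient of variation of interpolation is
#' \eqn{100 \cdot SD(\{d\}) / \mathrm{mean}(\{ii\})} (sample SD, n-1
#' divisor).  A perfectly interpolating method with identical patients
#' would give 0; patient variation keeps it positive.
#'
#' @param per_patient A data frame (or list of lists) with components
#'   `mrt_L`, `mrt_R`, `mrt_T`; at least 2 patients.
#' @return CV of interpolation in percent.
#' @examples
#' cv_interpolation(data.frame(mrt_L = c(100, 200), mrt_R = c(300, 400),
#'                             mrt_T = c(150, 350)))  # 35.36
#' @export
cv_interpolation <- function(per_patient) {
  if (!is.data.frame(per_patient)) {
    per_patient <- do.call(rbind, lapply(per_patient, as.data.frame))
  }
  stopifnot(all(c("mrt_L", "mrt_R", "mrt_T") %in% names(per_patient)))
  if (nrow(per_patient) < 2L) stop("need at least 2 patients")
  d <- per_patient$mrt_T - pmin(per_patient$mrt_L, per_patient$mrt_R)
  ii <- abs(per_patient$mrt_L - per_patient$mrt_R)
  if (any(ii == 0)) stop("undefined interpolation interval (MRT_L == MRT_R)")
  100 * stats::sd(d) / mean(ii)
}

#' CV of the root-mean-square error against reference MRTs
#'
#' \eqn{100 \cdot \sqrt{\sum_i (M_i - G_i)^2 / n} / (\sum_i G_i / n)} for a
#' method's MRTs \eqn{M} against reference (GDC) MRTs \eqn{G}.
#'
#' @param method_mrts,gdc_mrts Equal-length MRT vectors (minutes).
#' @return CV(rmse) in percent.
#' @examples
#' cv_rmse(110, 100)  # 10
#' @export
cv_rmse <- function(method_mrts, gdc_mrts) {
  if (length(method_mrts) != length(gdc_mrts)) stop("length mismatch")
  stopifnot(length(gdc_mrts) >= 1L, mean(gdc_mrts) > 0)
  100 * sqrt(mean((method_mrts - gdc_mrts)^2)) / mean(gdc_mrts)
}
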