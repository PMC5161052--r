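# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# one master seed spawning reproducible per-replicate sub-seeds (< 2^31)
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

#' Simulate a Poisson-noise time-activity curve
#'
#' Draws independent Poisson counts per frame with mean equal to the GDC
#' forward-model expectation ([expected_counts()]).  Non-integer
#' expectations are valid Poisson means; the simulated counts are integers.
#' No misregistration is injected: the only noise source is counting
#' statistics.
#'
#' @param params A [gdc_params()] object (the generating truth).
#' @param frames Frame layout; defaults to the clinical 89 x 1 min grid.
#' @param decay A [decay_config()]; the default simulates without decay.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @param poisson_noise If `FALSE`, return the noiseless expectations
#'   themselves as the TAC (useful for identifiability checks).
#' @return A `"tac"` object.
#' @examples
#' y <- simulate_tac(reference_cases()[["2T"]], seed = 42)
#' @export
simulate_tac <- function(params, frames = tac_frames(),
                         decay = decay_config(FALSE), seed = NULL,
                         poisson_noise = TRUE) {
  M <- expected_counts(params, frames, decay)
  if (any(M > 1e12)) stop("expected counts overflow (> 1e12)")
  counts <- if (poisson_noise) {
    with_seed(seed, stats::rpois(length(M), M))
  } else M
  tac(counts, frames)
}

#' Monte Carlo parameter-recovery study
#'
#' Generates `reps` Poisson-noise TACs from each generating parameter set,
#' refits each with the GDC model, and summarizes per-parameter precision
#' and accuracy.  The defaults reproduce the study design used to validate
#' the model: the nine clinical parameter sets, 10 replicates each on the
#' 89 x 1 min frame grid, radioactive decay not simulated (which both
#' raises the noise level relative to decayed counts and cross-checks the
#' decay-corrected clinical fits).
#'
#' For each of `t_A`, `a`, `b`, `alpha`, `beta`, `S`, `MRT_fast = a/b` and
#' `MRT_wo = alpha/beta` the summary reports: the generating ("clinical")
#' mean, the mean over all replicate fits, the mean of the per-case
#' coefficients of variation (each CV over the replicates of one case), the
#' accuracy error (100 x (mean simulated - mean generating) / mean
#' generating), and the two-tailed paired t-test p-value comparing the nine
#' per-case replicate means against the nine generating values.
#'
#' @param cases List of [gdc_params()] (default: [reference_cases()]).
#' @param reps Replicates per case, >= 2.
#' @param frames Frame layout.
#' @param decay A [decay_config()].
#' @param seed Master seed; spawns one sub-seed per (case, replicate), all
#'   recorded in the result for replay.
#' @param control [gdc_control()] for the refits.  The default uses the
#'   data-driven start plus two jittered restarts: the likelihood surface
#'   has a flat delivery-phase ridge on which a single simplex run
#'   occasionally strands, and restarts recover those replicates.
#' @param poisson_noise Passed to [simulate_tac()]; `FALSE` makes every
#'   replicate a deterministic refit of the noiseless curve.
#' @return An object of class `"recovery_study"`: a list with `fits`
#'   (per-replicate parameter data frame), `per_case` (per-case CVs),
#'   `summary` (per-parameter summary described above), `fisher_z_p`
#'   (paired t on Fisher-transformed model-data correlations, simulated vs
#'   clinical reference when available), `n_nonconverged`, and `seeds`.
#' @examples
#' \donttest{
#' st <- recovery_study(reps = 2, seed = 7)
#' summary(st)
#' }
#' @export
recovery_study <- function(cases = reference_cases(), reps = 10,
                           frames = tac_frames(),
                           decay = decay_config(FALSE), seed = 1L,
                           control = gdc_control(n_restarts = 3L),
                           poisson_noise = TRUE) {
  stopifnot(reps >= 2, length(cases) >= 1)
  if (is.null(names(cases))) names(cases) <- seq_along(cases)
  seeds <- matrix(derive_seeds(seed, length(cases) * reps),
                  nrow = length(cases), dimnames = list(names(cases), NULL))
  quantities <- c("t_A", "a", "b", "alpha", "beta", "S", "mrt_fast", "mrt_wo")
  rows <- list()
  n_bad <- 0L
  for (ci in seq_along(cases)) {
    p <- cases[[ci]]
    for (r in seq_len(reps)) {
      y <- simulate_tac(p, frames, decay, seed = seeds[ci, r],
                        poisson_noise = poisson_noise)
      fit <- suppressWarnings(gdc_fit(y, decay, control))
      if (!fit$converged) {
        n_bad <- n_bad + 1L
        next
      }
      q <- fit$params
      rows[[length(rows) + 1L]] <- data.frame(
        case = names(cases)[ci], rep = r,
        t_A = q$t_A, a = q$a, b = q$b, alpha = q$alpha, beta = q$beta,
        S = q$S, mrt_fast = q$a / q$b, mrt_wo = q$alpha / q$beta,
        fit_err_pct = fit$metrics$fit_err_pct,
        r_model = sqrt(1 - fit$metrics$one_minus_r2_pct / 100),
        stringsAsFactors = FALSE)
    }
  }
  fits <- do.call(rbind, rows)
  truth <- do.call(rbind, lapply(cases, function(p) {
    data.frame(t_A = p$t_A, a = p$a, b = p$b, alpha = p$alpha,
               beta = p$beta, S = p$S, mrt_fast = p$a / p$b,
               mrt_wo = p$alpha / p$beta)
  }))
  cv <- function(v) if (mean(v) == 0) 0 else 100 * stats::sd(v) / mean(v)
  per_case <- do.call(rbind, lapply(split(fits, fits$case), function(d) {
    cbind(data.frame(case = d$case[1L], n = nrow(d)),
          as.data.frame(lapply(d[quantities], cv)),
          mrt_fast_sd_min = stats::sd(d$mrt_fast))
  }))
  per_case <- per_case[names(cases)[names(cases) %in% per_case$case], ]
  case_means <- do.call(rbind, lapply(split(fits, fits$case), function(d) {
    as.data.frame(lapply(d[quantities], mean))
  }))
  case_means <- case_means[names(cases)[names(cases) %in% rownames(case_means)], ]
  summ <- do.call(rbind, lapply(quantities, function(qn) {
    clin <- truth[[qn]]
    simm <- case_means[[qn]]
    p_nd <- if (length(clin) >= 3L) {
      pt <- paired_tests(clin, simm)
      pt$t_p_two_tailed
    } else NA_real_
    data.frame(quantity = qn,
               clinical_mean = mean(clin),
               sim_mean = mean(fits[[qn]]),
               mean_within_case_cv_pct = mean(per_case[[qn]]),
               accuracy_err_pct = 100 * (mean(simm) - mean(clin)) / mean(clin),
               p_no_difference = p_nd,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- summ$quantity
  ref <- tryCatch(reference_cases(as = "data.frame"), error = function(e) NULL)
  fz <- NA_real_
  if (!is.null(ref) && setequal(names(cases), ref$case) &&
      length(cases) >= 3L) {
    r_clin <- sqrt(1 - ref$one_minus_r2_pct[match(names(cases), ref$case)] / 100)
    r_sim <- vapply(split(fits$r_model, fits$case)[names(cases)], mean,
                    numeric(1))
    fz <- tryCatch(fisher_z_compare(r_clin, r_sim), error = function(e) NA_real_)
  }
  structure(list(fits = fits, per_case = per_case, case_means = case_means,
                 truth = truth, summary = summ, fisher_z_p = fz,
                 n_nonconverged = n_bad, seeds = seeds,
                 reps = reps, decay = decay),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("Monte Carlo recovery study: %d case(s) x %d replicate(s)%s\n",
              nrow(x$truth), x$reps,
              if (x$decay$enabled) " (decay simulated)" else " (no decay)"))
  if (x$n_nonconverged > 0) {
    cat(sprintf("  %d non-converged replicate(s) excluded\n", x$n_nonconverged))
  }
  df <- x$summary
  df[-1] <- lapply(df[-1], signif, 4)
  print(df, row.names = FALSE)
  if (is.finite(x$fisher_z_p)) {
    cat(sprintf("fit-quality comparison (paired t on Fisher z of model-data r): p = %.3f\n",
                x$fisher_z_p))
  }
  invisible(x)
}

#' @export
summary.recovery_study <- function(object, ...) object$summary

#' Paired tests between clinical and simulated per-case values
#'
#' Two-tailed paired t-test and exact Wilcoxon signed-rank test of the
#' hypothesis of zero difference.  If every pairwise difference is exactly
#' zero, both p-values are 1 by convention; nonzero constant differences
#' (zero variance) make the t statistic undefined and are flagged with
#' `degenerate = TRUE` (t p-value `NA`).
#'
#' @param clinical,sim_means Equal-length numeric vectors, length >= 3.
#' @return List with `t_p_two_tailed`, `wilcoxon_p`, `degenerate`.
#' @examples
#' paired_tests(c(1, 2, 3), c(2, 3, 4.5))
#' @export
paired_tests <- function(clinical, sim_means) {
  if (length(clinical) != length(sim_means)) stop("length mismatch")
  if (length(clinical) < 3L) stop("need at least 3 pairs")
  d <- sim_means - clinical
  if (all(d == 0)) {
    return(list(t_p_two_tailed = 1, wilcoxon_p = 1, degenerate = FALSE))
  }
  degen <- stats::sd(d) == 0
  t_p <- if (degen) NA_real_ else
    stats::t.test(sim_means, clinical, paired = TRUE)$p.value
  w_p <- tryCatch(
    stats::wilcox.test(sim_means, clinical, paired = TRUE,
                       exact = length(d) <= 25)$p.value,
    warning = function(w) suppressWarnings(
      stats::wilcox.test(sim_means, clinical, paired = TRUE,
                         exact = FALSE)$p.value))
  list(t_p_two_tailed = t_p, wilcoxon_p = w_p, degenerate = degen)
}

#' Compare paired correlation coefficients via Fisher's z
#'
#' Transforms each correlation with \eqn{z = \mathrm{atanh}(r)} and runs a
#' two-tailed paired t-test on the z pairs.
#'
#' @param r_clinical,r_sim Correlations in (-1, 1), equal length.
#' @return Two-tailed p-value (1 when all pairs are identical).
#' @export
fisher_z_compare <- function(r_clinical, r_sim) {
  if (length(r_clinical) != length(r_sim)) stop("length mismatch")
  if (any(abs(c(r_clinical, r_sim)) >= 1)) stop("correlations must be in (-1, 1)")
  z1 <- atanh(r_clinical)
  z2 <- atanh(r_sim)
  if (all(z1 == z2)) return(1)
  stats::t.test(z2, z1, paired = TRUE)$p.value
}
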