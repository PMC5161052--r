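# shared helpers: noiseless TACs from the bundled reference cases and a
# small fast-to-fit parameter set for unit checks

noiseless_tac <- function(case, frames = tac_frames()) {
  simulate_tac(reference_cases()[[case]], frames, poisson_noise = FALSE)
}

small_params <- function() {
  gdc_params(t_A = 0.3, a = 1.5, b = 2, alpha = 0.9, beta = 0.01, S = 5e4)
}

# random valid GDC shape draws in the clinically relevant region
random_shapes <- function(n, seed) {
  with_seed_local(seed, replicate(n, list(
    a = stats::runif(1, 0.6, 8),
    b = stats::runif(1, 0.7, 12),
    alpha = stats::runif(1, 0.55, 0.98),
    beta = stats::runif(1, 0.001, 0.02)
  ), simplify = FALSE))
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
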