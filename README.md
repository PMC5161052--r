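# gdctac

Gamma distribution convolution (GDC) modelling of bolus-injection
time-activity curves from dynamic gamma-camera studies.

## The problem

After an intravenous bolus of a radiotracer such as ⁹⁹ᵐTc-MIBI, the
activity in an organ region of interest (ROI) rises over the first minutes
as tracer is delivered and distributes, then declines over hours as the
organ washes out.  The pharmacokinetic quantity of interest is usually the
mean residence time (MRT).  Classical washout-only models (biexponentials,
gamma variates) are maximal at their own start, cannot represent the rising
limb, and need many hours of data to pin down slow washouts.  `gdctac`
instead fits the *entire* curve with a closed-form convolution of two gamma
densities

```
GDC(a, b, α, β; τ) = GD_fast(a, b; τ) ⊗ GD_WO(α, β; τ)
                   = bᵃβᵅ/Γ(a+α) · e^{−bτ} τ^{a+α−1} · ₁F₁[α, a+α, (b−β)τ],   τ = t − t_A
```

— a fast delivery component (shape `a`, rate `b` per min), a slow washout
component (shape `α < 1`, rate `β`), an arrival offset `t_A`, and a count
scale `S`.  Mean residence times decompose exactly as
`t_A + a/b + α/β`; the organ measures are `MRT_fast = a/b` (delivery,
under a minute for thyroid MIBI) and `MRT_WO = α/β` (washout, hundreds of
minutes).  The package is aimed at nuclear-medicine and pharmacokinetic
modellers who need whole-curve MRT estimation from ~90 min of framed
counts, and a realistic simulator for stress-testing simpler washout
models.

It provides:

* numerically stable closed-form densities (`gdc_density()`,
  `edc_density()`, `gd_density()`) with a C++ confluent-hypergeometric
  kernel, plus MRT calculus (`gdc_mrt()`, `mrt_numeric()`);
* a decay-aware forward model for framed counts (`expected_counts()`,
  `decay_config()`) and a Poisson TAC simulator (`simulate_tac()`);
* Poisson-likelihood model fitting (`gdc_fit()`) with the usual S3
  methods (`coef`, `summary`, `predict`, `residuals`, `simulate`,
  `plot`);
* Monte Carlo parameter-recovery studies (`recovery_study()`) with
  per-case precision, accuracy and paired tests;
* washout-only comparators (`fit_e2()`, `fit_gv()` including a
  Tikhonov-regularized gamma variate) and comparison statistics
  (`cv_interpolation()`, `cv_rmse()`);
* nine bundled clinical-scale reference parameter sets
  (`reference_cases()`) from a three-patient thyroid ⁹⁹ᵐTc-MIBI series,
  and a small CLI (`inst/cli/gdctac.R`).

## Worked example

Simulate one Poisson-noise curve from a reference case (right thyroid lobe,
generating washout MRT 212.2 min) and refit it:

```r
library(gdctac)
p <- reference_cases()[["1R"]]
y <- simulate_tac(p, seed = 42)        # 89 one-minute frames, no decay
fit <- gdc_fit(y, control = gdc_control(n_restarts = 1))
print(fit)
```

```
GDC model fit (poisson_nll loss)
       t_A          a          b      alpha       beta          S 
1.8950e-09 8.2174e+00 7.8413e+00 8.6769e-01 4.1397e-03 2.3021e+06 
MRT fast 1.048 min, MRT washout 209.6 min
fit error 0.950% (corrected 0.984%), noise 1.054%, 1-R2 0.140%
```

The washout MRT (`α/β` = 209.6 min) lands within ~1.2% of the generating
212.2 min, and the fit error (~1%) is at the counting-noise floor.  Note
that `t_A`, `a` and `b` individually land far from the generating values
(0.334, 3.733, 5.211): with one-minute frames the delivery phase spans only
2–3 points and those three parameters trade off along a flat likelihood
ridge, while their combinations — the fitted curve, `a/b`, and especially
`α/β` — are stable.  See the methods vignette
(`vignettes/gdc-tac-modelling.Rmd`) for the full story.

A Monte Carlo check of the whole pipeline:

```r
st <- recovery_study(seed = 1)   # 9 cases x 10 Poisson replicates, no decay
print(st)
summary(st)["mrt_wo", ]          # precision/accuracy of the washout MRT
```

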