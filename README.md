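# weightdrive

Individual-based energy-balance analysis of long-term body-weight
records: what *drive* to eat does a multi-year weight history imply,
and how much do leptin and dieting suppress it?

## The model

Two state variables — the calories stored in adipose tissue, *C* [cal],
and plasma leptin, *L* [ng ml⁻¹] — evolve on widely separated time
scales:

    dC/dt = I − Q,    I = D − αL,    dL/dt = βC − γL

The latent input *D* [cal day⁻¹] is the eating drive (the collective of
physiological and psychological incentives to eat or stop eating);
leptin, produced in proportion to the fat store and cleared at
γ = 40.1 day⁻¹ (24.9-minute half-life), damps intake through αL.
Expenditure decays slowly, Q(t) = Q₀e^(−εt), and weight is proportional
to the store, C = ρδW (ρ = 3500 cal lb⁻¹, δ the body-fat fraction).
Because leptin relaxes in minutes while weight relaxes over years, the
system lives on the quasi-steady manifold L = βC/γ, where the weight
trajectory has the closed form W(t) = A − B·e^(−εt).

The package provides:

* `integrate_full()` / `integrate_qss()` — stiff-capable simulation of
  the full system and its scalar reduction;
* `fit_weight_model()` / `fit_piecewise()` — bounded multi-start
  nonlinear least squares on the closed form (with a
  variable-projection polish), including a two-regime expenditure
  schedule with a continuity constraint at the transition;
* `reconstruct_drive()` — month-by-month inversion of the calorie
  balance for the latent drive;
* `drive_deficit()`, `period_statistics()`, `diet_ttest()`,
  `effect_percentages()`, `cross_correlation()`,
  `diet_effect_report()` — the dieting-effect analysis;
* `scenario_spec()` / `scenario_preset()` / `make_weight_series()` — a
  synthetic generator of subject-like records (yoyo diet cycles,
  stationary weight fluctuations) for end-to-end testing;
* `run_pipeline()` — fit → reconstruct → diet statistics in one call,
  with CSV/JSON outputs.

Fits carry broom-style `tidy()`/`glance()`/`augment()` methods and
`autoplot()` figures. See the vignette
(`vignettes/energy-balance-drive.Rmd`) for the methods.

## Worked example

```r
library(weightdrive)

spec   <- scenario_preset("subject_A_like", seed = 1)  # 80-month record
series <- make_weight_series(spec)
result <- run_pipeline(series$weights, series$schedule, seed = 1)
result$report
#> <diet_effect_report>
#>   baseline drive outside diets: 2046 (sd 201) cal/day over 55 months
#>   8 dietary periods, mean deficit 122 (sd 39) cal/day
#>   one-sided t-test (deficit > 0): t = 8.31, p = 3.561e-05
#>   effect on the drive: dieting 6.0%, leptin 0.04%
```

Reading: outside its dietary periods this synthetic subject's
reconstructed drive averages ~2050 cal/day; during the eight dietary
periods the drive drops by 122 cal/day on average, an effect that a
one-sided one-sample t-test on the per-period means finds decisively
positive (p ≈ 4·10⁻⁵) and that amounts to ~6% of the regular drive.
(Deficit magnitudes scale with the fitted body-fat fraction, which a
weight record alone does not identify — fix it with `fix_delta` for
cross-subject comparisons.) `autoplot(result$report)` shows the
cross-correlation of the deficit with the dietary block function,
whose skew toward negative shifts quantifies anticipation: the drive
falls before a period formally starts.

Reference worked-example statistics reproduced by the test suite
include the clearance rate ln 2/24.9 min = 40.1 day⁻¹, the calibration
β = γL̄/(ρδW̄) = 5.78×10⁻³ at (L̄ = 20.3, δ = 0.316, W̄ = 127.4), the
per-period deficit summaries 267 ± 87 and 160 ± 82 cal/day with their
one-sided p-values (< 0.0005 and 0.009), and the percentage effects
12% / 0.3% / 1%.

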