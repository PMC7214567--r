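# deadtime

Dead-time correction and resolving-time estimation for paralyzable gamma
detectors, in R.

## The problem

Quantitative gamma-camera imaging after radionuclide therapy (e.g. with
¹³¹I or ¹⁷⁷Lu) runs the detector at count rates where a substantial
fraction of events is lost to dead time: after each detected — or merely
arriving — photon the detector is unresponsive for a resolving time τ of
order a microsecond. For a *paralyzable* detector every arrival extends
the dead period, so the observed count rate is

```
R' = Rt · exp(−Rt · τ)
```

where `Rt` is the rate that would be recorded without losses. `R'` peaks
at `R'max = (e·τ)⁻¹` (reached at `Rt = 1/τ`) and then falls again, so the
relation is invertible only on the sub-maximum branch. The closed-form
inverse is the principal branch of the Lambert W function:

```
Rt = −W₀(−R'·τ) / τ ,        A = Rt / C
```

with `C` the sensitivity (count rate per unit activity) of the energy
window. The package implements this inversion both exactly (a
branch-point-seeded Halley solver) and as the N-term Taylor series of
`W₀` (default N = 10), plus everything needed to *calibrate* it:

* **dual / triple-source method** — τ from two sources measured alone and
  together, `τ = 2R'₁₂/(R'₁+R'₂)² · ln((R'₁+R'₂)/R'₁₂)`, scheduled over a
  whole decaying measurement series;
* **graphical method** — unweighted least squares of `ln(R'/A)` against
  `A` for a decaying source, whose intercept is `ln C` and slope `−C·τ`;
* **MCR method** — `τ = (e·R'max)⁻¹` from the observed peak rate;
* **energy-window relation** — `τ_EW = τ_OW / w_f^η` linking the
  photopeak-window dead time to the open-window (whole-spectrum) value
  through the window fraction `w_f`, with `η` estimable from calibration
  data, and window-fraction-versus-rate diagnostics for pulse pile-up;
* a **synthetic counting-experiment simulator** (decaying ⁹⁹ᵐTc sources,
  60-s frames, 300-s backgrounds, Poisson noise, rate-dependent window
  fraction, optional high-rate breakdown) so every estimator can be
  validated without camera data;
* delimited-text **series I/O** and a small **command-line interface**.

Internal units are seconds, cps and Bq throughout; print methods and the
CLI use the field's customary µs, kcps and MBq.

## Worked example

Simulate an intrinsic triple-source calibration (three ⁹⁹ᵐTc sources of
125, 125 and 250 MBq measured through ~29 h of decay; 49 source frames)
and estimate the detector parameters:

```r
library(deadtime)

series <- simulate_series(make_intrinsic_preset(seed = 7))
series
#> <measurement series: 102 frames (4 background), 1 detector(s), 2 window(s), 3 source(s)>

graphical_fit(series, "det1", "OW")
#> Graphical dead-time fit (unweighted LS of ln(R'/A) vs A)
#>   sensitivity C = 0.7802 kcps/MBq (SE 0.00012)
#>   dead time tau = 1.3 us (SE 0.0015)
#>   R^2 = 0.999927; points used = 49, excluded = 0

sched <- triple_source_schedule(series, "det1", "OW")
sprintf("dual-source mean tau: %.3f us (sd %.3f, n = %d)",
        mean(sched$tau) * 1e6, sd(sched$tau) * 1e6, nrow(sched))
#> "dual-source mean tau: 1.328 us (sd 0.186, n = 17)"

window_fraction_series(series, "det1", "Tc")
#> Window-fraction fit: -9.51% per 100 kcps (SE 0.025), base fraction 0.6155, n = 49
```

The graphical fit recovers the generating parameters (C = 0.78 kcps/MBq,
τ = 1.30 µs) within its reported standard errors; the 17 dual-source
estimates agree with it on average but scatter more, which is why the
single-line graphical fit is preferred. The photopeak window fraction
declines by 9.5 percentage points per 100 kcps — the pile-up effect that
makes photopeak-window dead times geometry-dependent.

With the calibration in hand, correcting a clinical reading is one call:

```r
fit <- graphical_fit(series, "det1", "OW")
correct_rate(150e3, fit$tau) / 1e3       # 192.7 kcps true rate
estimate_activity(150e3, fit$tau, fit$sensitivity) / 1e6  # 247.0 MBq
```

A shell interface wrapping the same functions is installed at
`system.file("exec", "deadtime.R", package = "deadtime")`, with
subcommands `simulate`, `fit-graphical`, `fit-dualsource`, `fit-mcr`,
`correct`, `window-fraction` and `report`.

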