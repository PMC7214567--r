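---
title: "Dead-time correction for paralyzable gamma detectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dead-time correction for paralyzable gamma detectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deadtime)
```

## The model

Modern gamma cameras behave as *paralyzable* counting systems: every
photon arriving at the crystal — whether or not it ends up recorded —
renders the detector unresponsive for a resolving time $\tau$, and an
arrival during a dead period extends it by another $\tau$. The observed
count rate is therefore

$$R' = R_t\,e^{-R_t\tau},$$

where $R_t$ is the true (loss-free) rate. $R'$ rises to a maximum
$R'_{\max} = (e\tau)^{-1}$ at $R_t = \tau^{-1}$ and falls again beyond
it, so every observed rate below the maximum corresponds to **two** true
rates. Quantification is only possible on the sub-maximum branch, where
the closed-form inverse is the principal branch of the Lambert $W$
function:

$$R_t = -\frac{W_0(-R'\tau)}{\tau},
  \qquad A = \frac{R_t}{C}\,F\,e^{\mu_e d},$$

with $C$ the sensitivity of the energy window (cps/Bq) and the optional
factors $F$ and $e^{\mu_e d}$ (both default 1) absorbing tissue
background and absorption for non-point-source geometries. Dead time is
a **whole-detector** property: the losses in any energy window are
driven by the full spectrum hitting the crystal, i.e. by the open-window
rate.

Key modelling assumptions: a single, rate-independent $\tau$ per
detector; losses described purely at rate level (no event-level
electronics); and background handled by simple subtraction of a pooled
measured ambient rate.

## Numerical inversion

`correct_rate()` offers two paths.

* **Exact** (the reference): $W_0$ on $[-1/e, 0]$ by Halley iteration,
  seeded with the branch-point expansion
  $w \approx -1 + p - p^2/3 + 11p^3/72$, $p = \sqrt{2(1 + ez)}$, for
  $z < -0.25$ and with $w_0 = z$ otherwise. Within $10^{-6}$ of the
  branch point the expansion itself is returned (its error is $O(p^4)$
  there, while Halley's denominator degenerates). The solver is verified
  against an independent bisection in the test suite; round-tripping
  through the forward model is exact to $10^{-9}$ relative for
  $R'\tau \le 0.95/e$.
* **Truncated series**: $-W_0(-x) = \sum_{n\ge1} n^{n-1}x^n/n!$ cut at
  $N$ terms (default $N = 10$). With the loss fraction defined as
  $1 - R'/R_t$, the $N=10$ error is below 0.5% up to 30% losses and
  1.14% at exactly 40% losses; accuracy improves monotonically with $N$.

Observed rates with $R'\tau > 1/e$ exceed the theoretical maximum and
raise an error rather than being clamped: a single reading cannot reveal
whether the detector sits above or below the peak, and silently clamping
would fabricate a branch choice. Rates within the top 0.1% of the
maximum (configurable via `branch_margin`) are corrected but flagged
with a warning, because the two branches coincide at the peak and
floating-point noise can flip sides.

## Estimating $\tau$ and $C$

**Dual-source method.** With net rates $R'_1$, $R'_2$, $R'_{12}$ of two
sources measured alone and together,

$$\tau = \frac{2R'_{12}}{(R'_1+R'_2)^2}\,
         \ln\!\frac{R'_1+R'_2}{R'_{12}}.$$

This is exact for equal sources under the noiseless model. For unequal
sources the error is second order; expanding around the equal split
gives a relative error $\approx \delta^2(4 - R_t\tau)(1 - R_t\tau)$ with
$\delta$ the deviation of the single-source share from $1/2$, i.e. up to
four times the leading-order figure
$(R_{t,1}-R_{t,2})^2/\bigl(4(R_{t,1}+R_{t,2})^2\bigr)$ at low rates.
Over the customary validity band (single-source share 44–55%, combined
observed rate 35–95% of $R'_{\max}$) the exact worst case, which
`scripts/acceptance.R` recomputes, is 1.18% at the low-rate,
most-unequal corner — slightly above the 1% often quoted for this
band. `triple_source_schedule()` applies the formula across a series
acquired in the pattern 1, 2, 1+2, 3, 1+2+3: every combined frame whose
source set splits into two measured disjoint subsets yields one
estimate, the component frames matched by nearest acquisition time and
their rates decay-aligned (scaled by the activity ratio between the
combined frame's time and their own — a $\le 1\%$ linearisation for
⁹⁹ᵐTc frames minutes apart).

**Graphical method.** From the model, $R'/A = C e^{-C\tau A}$, so
$\ln(R'/A)$ is linear in $A$ with intercept $\ln C$ and slope $-C\tau$.
`graphical_fit()` runs an *unweighted* least-squares line through all
points — deliberately making no low-rate "no-loss" assumption — and
back-transforms; standard errors come from first-order (delta-method)
propagation of the linear fit's coefficient covariance. Points with
non-positive net rate or activity, and points beyond a user-supplied
model-validity cutoff, are excluded and counted, never silently
dropped. The cutoff is manual by design: real cameras leave the
paralyzable regime through a step-like breakdown whose onset is best
judged by the physicist, so no automatic changepoint detection is
attempted.

**MCR method.** `tau_from_mcr()` inverts $R'_{\max} = (e\tau)^{-1}$ when
only the peak of the measured count-rate curve is known.

**Energy windows and pile-up.** A photopeak window sees an *apparent*
dead time $\tau_{EW} = \tau_{OW}/w_f^{\eta}$, where
$w_f$ is the window fraction. $\eta = 1$ corresponds to an ideal
counting system; pulse pile-up pushes events out of the photopeak as the
rate grows, which both inflates $\eta$ (calibration data of the kind
shipped in the presets imply $\eta \approx 1.83$, recoverable with
`estimate_eta()`) and makes $w_f$ decline roughly linearly with the
open-window rate. `window_fraction_series()` measures that decline as
the slope of an unweighted linear fit, reported in percentage points per
100 kcps. The practical consequence, reflected in the package's design:
correct with the open-window $\tau$ and track the window fraction,
rather than trusting a photopeak-window $\tau$ across geometries.

## The simulator

`simulate_series()` generates synthetic calibration experiments at rate
level: per frame, the open-window true rate is
$\sum_s C_{OW}\bar A_s + b_{OW}$ (with $\bar A_s$ the exact integral
average of the decay law over the frame — unbiased for long frames on
fast-decaying sources), the observed rate follows the paralyzable model,
each photopeak window gets the open-window observed rate times its
linear, clipped-to-$[0,1]$ window fraction plus its own ambient rate,
and counts are Poisson draws of rate × duration under a caller-isolated
seed. Two deliberate choices:

* **Noise off means exact.** With `poisson_noise = FALSE` the emitted
  counts are the (generally fractional) expectations, so noiseless
  series lie on the model curve to machine precision and
  parameter-recovery tests can assert $10^{-9}$ relative accuracy.
  Rounding to integers would inject up to $\sim10^{-4}$ quantisation at
  low rates and mask genuine regressions.
* **Zero ambient background by default.** Simple subtraction of a
  measured background is only first-order exact once the ambient rate
  passes through the nonlinearity, so the presets default to quiet-room
  conditions; `background_ow` switches a constant ambient rate on for
  studying exactly that bias (an unsubtracted or unsubtractable
  background inflates the fitted $\tau$).

`make_intrinsic_preset()` encodes a reference intrinsic calibration:
sources of 125, 125 and 250 MBq (⁹⁹ᵐTc half-life 6.01 h), 60-s source
frames, 300-s bracketing backgrounds, $C_{OW} = 0.78$ kcps/MBq,
$\tau = 1.30$ µs, photopeak base fraction $0.48/0.78$ declining 9.5
points per 100 kcps. The schedule holds two full triple-source sets plus
thirteen dual-source sets spread over ~28.7 h, i.e. 49 source frames and
17 dual-source estimates, with the single sources decaying to ~4.5 MBq —
the span (7 half-lives exceed 40 h) over which a decaying-source
calibration covers its full rate range. `make_phantom_preset()` encodes
an extrinsic scatter-phantom analogue: two 1.4 GBq sources,
$\tau = 0.92$ µs, and — since collimated scatter-geometry sensitivities
must be chosen rather than tabulated — a field-realistic LEHR
open-window sensitivity of 0.09 kcps/MBq with base window fraction 0.55
declining 5.1 points per 100 kcps. An optional breakdown regime
multiplies all rates by $1 - $ `drop_fraction` above an observed
open-window threshold, purely phenomenologically, to exercise
model-validity filtering; affected frames are labelled in the series
metadata.

What the simulator does **not** emulate: spectral physics (energy
resolution, photopeak broadening, scatter continua), the window-fraction
*increase* observed beyond breakdown on real cameras, detector spatial
response, and any rate dependence of $\tau$ itself. Passing tests
therefore demonstrate correctness of the estimators and the inversion
under the stated model, not robustness to every instrumental pathology.

## Problem sizes and reproducibility

The replicate studies in the test suite use 50–200 seeded Poisson
replicates of the 49-frame intrinsic preset, enough for stable 3-SE
coverage checks while keeping the default suite quick. All randomness
flows through explicit integer seeds; simulation restores the caller's
RNG state, and identical seeds give bit-identical series and CLI
outputs.

## Known limitations

* Corrections are undefined above $R'_{\max}$; the package refuses them.
* $\tau$ is constant per detector; slow drifts with rate or activity are
  not modelled, and photopeak-window $\tau$ values transfer poorly
  between geometries (use the open-window value plus window fraction).
* Decay alignment in the dual-source schedule is a first-order rate
  scaling; for sources decaying appreciably between paired frames it
  leaves a second-order residual (~0.1% for ⁹⁹ᵐTc at 60-s spacing).
* Standard errors assume the unweighted log-scale fit's homoscedastic
  error model; Poisson weighting is deliberately out of scope.
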