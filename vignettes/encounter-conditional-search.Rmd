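---
title: "Encounter-conditional search analysis: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encounter-conditional search analysis: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`arsearch` asks an event-level question of foraging GPS data: does the
forager condition its movement on prey encounters (area-restricted search,
ARS), or move by a non-conditional Lévy flight? This vignette documents the
models, every tunable that matters, the numerical choices, and what the
package's validation does and does not establish.

## The observation models

Fixes arrive at a nominal 10 s cadence. Each consecutive pair within a trip
gives a step: size `r[t]` in metres (Euclidean, planar), heading `theta[t]`
in (-pi, pi] by `atan2`, and unit-scaled turning angle
`delta[t] = min(|a - b|, 2*pi - |a - b|) / pi` in [0, 1], where `a`, `b` are
the headings of steps `t` and `t - 1` (a 90-degree right turn equals a
270-degree left turn, so only the wrapped magnitude is kept).

Turning angle is bounded, so it is modelled by a Beta regression with a
logit link on the mean; step size is positive and right-skewed, so it is
modelled log-normally:

- `delta[t] ~ Beta(mu[t] nu, (1 - mu[t]) nu)`,
  `mu[t] = logit^-1(psi0 + sum_s psi[s] E[t-s])`;
- `r[t] ~ LogNormal(eta[t], omega)`,
  `eta[t] = phi0 + sum_s phi[s] E[t-s]`,

with `s = 1..S` and `S = 90` by default (15 minutes of history at 10 s per
step). The lag coefficients are the scientific quantities: `psi[s] > 0`
means an encounter `s` steps ago raises the expected turning angle now;
`phi[s] < 0` means it lowers speed. A strict Lévy forager corresponds to
`psi[s] = phi[s] = 0` with uniform turning angles, i.e. `psi0 = 0` and
`nu = 2` (Beta(1, 1)). `first_crossing_lag()` summarises a fitted curve by
the first lag whose 90% credible interval reaches zero: effects are
credibly non-zero for all shorter lags.

Assumptions worth keeping in view: encounters act additively on the link
scale and identically at every occurrence; lags do not interact; the
dispersion parameters are constant over time and trips; and both hunters'
data are pooled (no hierarchical structure — a deliberate simplification at
this sample size).

## Priors, sampling and diagnostics

Priors are weakly informative: intercepts Normal(0, 5), lag coefficients
independent Normal(0, 1), dispersions Exponential(0.1), AR-1 coefficient
Normal(0, 1). At roughly 6,600 observations the lag-coefficient posteriors
are dominated by the likelihood. Lag coefficients are a priori independent;
an optional random-walk smoothing prior across adjacent lags
(`lag_priors(smooth_sd = )`) is available but off by default, so the
reported curves are not smoothed by construction.

The posteriors here are smooth, unimodal and (at these sample sizes) close
to Gaussian, which the sampler exploits: BFGS finds the posterior mode
using analytic gradients, the negative inverse Hessian gives a Laplace
approximation, and independence Metropolis–Hastings with a multivariate-t
proposal (df 8, covariance inflated 1.1x) centred on the mode corrects the
approximation, so retained draws target the exact stated posterior.
Acceptance rates run 25–55% for the 92-parameter lag models and higher for
the 2–4-parameter distribution fits. Multiple chains give a split R-hat;
fits are flagged non-converged (with a warning, never a silent failure)
when acceptance falls below 2% or max R-hat exceeds 1.1. Defaults are 4
chains x 1,000 kept draws; the package's own validation uses 2 x 500,
which recovers 90-lag curves with nominal-coverage intervals.

"Significant" throughout means the central 90% credible interval excludes
zero, and interval level is a parameter of the summaries, not of the fits.

## Numerical choices

- **Stationarity threshold** `epsilon = 0.5` m per step (below GPS noise):
  shorter steps get no heading; the last valid heading is carried forward
  as the reference for the next turning angle, and turning angles without a
  defined reference are dropped from likelihoods (not zero-filled).
- **Endpoint squeeze**: the Beta density is undefined at 0 and 1, and
  observed turning angles hit both (straight steps, exact reversals).
  Values exactly 0 or 1 are mapped by `(d (n - 1) + 0.5) / n`; interior
  values are untouched.
- **Zero-step floor** `r_floor = 0.05` m before the log-normal likelihood,
  since waiting produces exact zeros whose log is undefined. Both `epsilon`
  and `r_floor` are user-settable.
- **Cadence gaps**: a gap of more than one missed fix splits a trip into
  segments; steps, turning angles and lag histories never span a split, and
  lags reaching before a segment start are zero.
- **Projection**: a local tangent plane at the track centroid (plate
  carrée scaled by cos of the centroid latitude). Over the few-kilometre
  spans of a hunting trip the distortion is far below GPS error, and the
  mapping is exactly invertible, which the tests exploit.
- **Annotation matching**: an annotation flags the nearest fix in time,
  ties to the earlier fix; annotations outside the track's range by more
  than 10 s (default tolerance) are an error rather than silently dropped.
- **Patch convention**: with window `W = 50`, the steps `k+1 .. k+50` after
  an encounter at step `k` are in-patch; the encounter step itself is not.
- **Truncated distributions**: likelihood `f(x) / F(tau)` on `x <= tau`,
  with `tau` a free parameter bounded below by the sample maximum and given
  a uniform prior on `[max(r), 2 max(r)]` — the truncation point is
  estimated, not fixed. The Pareto lower bound is the smallest (floored)
  observed step. WAIC is reported on the deviance scale, and its
  `lppd`/`p_waic` terms are computed with a log-sum-exp guard.
- **Lévy convention**: `levy_alpha` is the density exponent
  (`f(x) ~ x^-alpha`, `alpha > 1` for a normalisable tail); the Pareto
  shape parameter equals `alpha - 1`. Simulated Lévy steps use a truncated
  Pareto (default truncation 500 m) to keep paths finite; the truncation is
  recorded in the config.

## Design choices at genuinely open points

- The AR-1 robustness variant adds the previous outcome, link-transformed
  and centred, as a regressor on the link scale with coefficient `rho` —
  an observation-driven autoregression chosen so the plain model is nested
  at `rho = 0`. Its first row per segment (no predecessor) is dropped.
- The encounter-type split duplicates the lag curves for hit versus
  non-hit encounters with a shared intercept and dispersion, since post-hit
  behaviour may reflect item recovery rather than search.
- Patch regressions use a linear model for the continuous outcomes — the
  slope then *equals* the in/out mean contrast exactly — and a logistic
  model for encounter occurrence on the previous step's movement, because
  the outcome is binary. The logistic choice is an assumption of this
  package; its slopes are on the log-odds scale.
- Shots/hits/recovered counts are read from annotation metadata when
  present and reported absent otherwise — never silently zero.

## What the simulator emulates, and what it does not

`sim_config()` defaults define the reference study conditions: 6 trips x
1,100 steps at 10 s (≈6,600 fixes), encounter prevalence near 1.5% of
fixes, Beta turning angles with `psi0 = -1`, `nu = 4`, log-normal steps
with `phi0 = 0.64`, `omega = 0.9` (median step ≈1.9 m, i.e. ≈0.7 km/h),
and smooth exponential-decay lag curves
`psi[s] = a exp(-s/30)`, `phi[s] = -b exp(-s/30)` with `a = 1`, `b = 0.6` —
effects that decay over roughly 60–90 lags, the time scale the analysis is
designed to resolve. The prey field is a Thomas cluster process (40
clusters/km², 25 items/cluster, 30 m scatter) with a 20 m detection
radius, calibrated once so ARS-mode prevalence lands near 1.5%. In ARS mode
the agent's own encounters feed back through the lag curves and encountered
prey are removed; in Lévy mode encounters are recorded but ignored.

The simulator deliberately omits features of real tracks: GPS measurement
noise, terrain constraints (the ridge-line and stream-bed route fidelity of
real hunters), inter-individual differences, memory beyond the lag horizon,
and diurnal rhythm. Passing recovery tests therefore shows the estimators
are correct *under the stated generative model* — it does not show the
model is adequate for any particular field data set, which is what the
robustness variants and WAIC comparisons are for on real data.

## Validation scales

The test suite validates at reduced but meaningful sizes: lag-curve
recovery and crossing-lag location over 20 simulated data sets of 6 x 1,100
steps with known 40-lag step curves (psi = 0.8, phi = -0.6) at 2 chains x
500 draws; null calibration on 3 data sets per model (90 null coefficients
each, expecting ~10% false exclusion from 90% intervals); the Lévy special
case on a 3,000-step uniform-angle track; WAIC against an independent
brute-force implementation to 1e-10 and model selection at n = 5,000 per
generating family; distribution-parameter recovery at n = 10,000
(tolerances ±0.05 on log-normal mu/sigma, ±0.1 on the Pareto shape); patch
statistics exactly on constructed data and at ~90% nominal coverage over
100 null logistic fits. `scripts/acceptance.R` re-runs the same pipeline
end to end and emits the quantities as JSON.

## Known limitations

- The independence-MH sampler is efficient precisely because these
  posteriors are near-Gaussian; it is not a general-purpose sampler, and
  strongly multimodal extensions (e.g. mixture observation models) would
  need different machinery.
- Lag effects are estimated per coefficient; without smoothing, curves at
  small encounter counts are noisy, and the first-crossing summary inherits
  that noise.
- Pooling trips and individuals means coefficients are population averages
  over the sampled hunts; extending to hierarchical (per-individual) curves
  is natural but out of scope.
- Planar kinematics ignore elevation; distances are 2-D, which
  understates effort on steep terrain (elevation range is reported
  separately per trip).
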