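# arsearch

Event-level analysis of encounter-annotated GPS foraging tracks, for
movement and behavioural ecologists asking *how* a forager searches: by
non-conditional Lévy flights, or by adaptive **area-restricted search
(ARS)** in which prey encounters trigger tighter turning and slower
movement. Distribution-level analyses (fitting a step-length tail) cannot
separate the two, because ARS interacting with patchy prey produces
Lévy-like gross movement; `arsearch` implements the event-level alternative:
regress movement at time *t* on encounters at lagged time steps.

## The models

A track is a sequence of fixes (x[t], y[t]) at a fixed 10 s cadence, with a
binary encounter flag E[t]. Steps are converted to polar form:

- step size `r[t] = sqrt((x[t]-x[t-1])^2 + (y[t]-y[t-1])^2)` (a velocity
  proxy at fixed cadence),
- heading `theta[t]` by quadrant-adjusted arctangent (`atan2`),
- unit-scaled turning angle
  `delta[t] = min(|a-b|, 2*pi - |a-b|) / pi` for consecutive headings, in
  [0, 1].

Turning angle follows a lagged Beta regression

    delta[t] ~ Beta(mu[t] * nu, (1 - mu[t]) * nu)
    mu[t]    = logit^-1( psi[0] + sum_{s=1..S} psi[s] * E[t-s] )

and step size a lagged log-normal regression

    r[t]   ~ LogNormal(eta[t], omega)
    eta[t] = phi[0] + sum_{s=1..S} phi[s] * E[t-s]

with S = 90 lags (15 min) by default. ARS predicts `psi[s] > 0` and
`phi[s] < 0` at short lags; a strict Lévy forager is the special case
`psi[s] = phi[s] = 0` with uniform turning angles (`psi[0] = 0, nu = 2`).
Fits are Bayesian (weakly informative priors; posterior mode + Laplace
approximation corrected by independence Metropolis–Hastings, with split
R-hat diagnostics), summarised by posterior medians and central 90%
credible intervals. `first_crossing_lag()` reports how many lags the
effects remain credibly non-zero; AR-1 and encounter-type-split variants
probe robustness. Six candidate step-size distributions (folded-normal,
log-normal, Pareto; plain and upper-truncated) are compared by WAIC, and
patch-conditional regressions summarise movement inside versus outside
"patches" (steps within W = 50 steps of an encounter).

A forager simulator closes the loop: `simulate_forager()` moves an agent
through a clustered (Thomas-process) prey field either by the
encounter-conditional heuristics above ("ars") or as a truncated-Pareto
Lévy flight ("levy"), so every estimator can be validated by parameter
recovery against known ground truth.

## Worked example

```r
library(arsearch)

## simulate an encounter-conditional forager: 6 trips x 1,100 fixes at 10 s
sim <- simulate_forager(sim_config(seed = 42), mode = "ars")
sim
#> <ars_sim> ars mode: 6 trips, 6600 fixes, 114 encounters ( 1.73% )

hunt_summary(sim$track)[, 1:7]
#> # A tibble: 6 x 7
#>   trip_id n_fixes dist_km duration_hr avg_speed_kmh elev_change_m n_encounters
#> 1 sim_1      1100    2.22        3.05         0.727            NA           28
#> 2 sim_2      1100    2.31        3.05         0.758            NA           24
#> 3 sim_3      1100    2.36        3.05         0.773            NA           25
#> 4 sim_4      1100    2.71        3.05         0.888            NA           11
#> 5 sim_5      1100    2.75        3.05         0.901            NA            9
#> 6 sim_6      1100    2.49        3.05         0.816            NA           17

## lagged Beta regression of turning angle on encounters, 90 lags back
polar  <- to_polar(sim$track)
design <- build_lag_design(polar, "delta", S = 90)
fit <- fit_beta_lag(design, sampler = sampler_config(chains = 2, iter = 500,
                                                     warmup = 150, seed = 1))
glance(fit)
#> # A tibble: 1 x 8
#>   model variant outcome     n     S accept_rate rhat_max converged
#> 1 beta  plain   delta    5696    90       0.286     1.05 TRUE

first_crossing_lag(fit)
#> [1] 32
```

The crossing lag of 32 says encounters credibly raise turning angle for
about 32 steps (~5 min) under the simulator's default decay curve; on real
tracks this is the number to compare against the lag plot
(`autoplot(fit)`). Patch-level contrasts carry the same signal as simple
slopes — turning angle is higher and step size lower inside patches:

```r
patched <- label_patches(polar, W = 50)
rbind(regress_on_patch(patched, "delta"), regress_on_patch(patched, "r"))
#> # A tibble: 2 x 7
#>   outcome predictor model  estimate conf.low conf.high     n
#> 1 delta   in_patch  linear    0.164    0.154     0.174  5696
#> 2 r       in_patch  linear   -1.10    -1.21    -0.999   6594
```

Real data enter through `read_gpx_track()` (GPX 1.1 trackpoints),
`read_gpx_waypoints()` / `read_annotations_csv()` and
`align_encounters()`; `run_pipeline()` (or the `inst/cli/ars-search.R`
wrapper) runs the whole analysis and writes CSV reports.

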