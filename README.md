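# kalmag

Bayesian observer models for magnitude estimation: central tendency,
sequential dependence, and the beliefs about temporal continuity that link
them.

## The problem

In magnitude reproduction experiments (duration, distance, angle), responses
show two robust biases: *central tendency* — overestimation of small and
underestimation of large magnitudes — and *sequential dependence* — the
current error depends on the previous stimulus. Both follow from Bayesian
perception, but their relative size depends on what the observer implicitly
believes about how stimuli are generated over time: independently from a
fixed distribution, as a random walk, or — in between — drawn around a mean
that itself drifts.

`kalmag` implements the three corresponding observer models as one discrete
Kalman filter in Weber–Fechner log space, `z = ln(1 + d/d0)`, over the
two-dimensional state (current stimulus `x`, distribution mean `m`):

    x_i = m_{i-1} + eps_x,   eps_x ~ N(0, v)
    m_i = m_{i-1} + eps_m,   eps_m ~ N(0, q)
    z_i = x_i     + eta,     eta   ~ N(0, r)

with `F = [[0,1],[0,1]]`, `H = [1,0]`, `Q = diag(v, q)` and `r` normalized
to 1. The *static* model is the `q = 0` constraint (fixed prior, zero
sequential dependence), the *simple iterative* model is `v = 0`
(exponential smoothing; for random stimulus order its sequential dependence
follows the parabola `s = (1 − c)·c`, maximum 0.25 at `c = 0.5`), and the
full *two-state* model spans everything between. Free parameters: the
variance ratios `v/r` and `q/r` plus a log-domain shift `Δx`; steady-state
estimates are back-transformed as `d = d0·(exp(x̂ + Δx) − 1)`.

The package provides:

* **Generators** for i.i.d., bounded random-walk, and two-state stimulus
  sequences, histogram matching between them (`match_histograms()`), and a
  synthetic two-condition cohort emulating a 14-subject, 400-trial
  reproduction study (`make_synthetic_study()`).
* **Bias metrics**: `central_tendency()`, `sequential_dependence()`,
  `partial_correlation()`, `lagged_dependence()`, `group_summary()`.
* **Fitting and selection**: linear-domain least squares with multi-start
  Levenberg–Marquardt (`fit_model()`), linearized confidence intervals,
  windowed leave-one-out cross-validation for time series
  (`loo_timeseries()`), zero-free-parameter cross-condition prediction
  (`predict_condition()`), `r_squared()` and `binned_average()`.
* **I/O and pipeline**: CSV trial tables (`read_trials()`,
  `write_trials()`), study manifests, and `run_pipeline()` for the whole
  per-subject analysis.

## Worked example

Simulate one subject of the default study (a 400-trial bounded random walk
of durations between 400 and 1900 ms, plus the same values in scrambled
order), quantify the biases, fit the two-state model to the randomized
session, select among the nested models, and predict the random-walk
session from the randomized-session parameters:

```r
library(kalmag)

study <- make_synthetic_study(default_study_config(n_subjects = 1, seed = 42))
rnd <- study$trials[["s01.randomized"]]
wlk <- study$trials[["s01.random_walk"]]

bias_summary(rnd)
#> <bias_summary> c = 0.270, s = 0.028, partial r(prev) = 0.063, partial r(curr) = -0.514

fit <- fit_model(rnd, "two_state")
fit
#> <observer_fit> two_state model, 400 trials, sse = 4.27734e+06
#>   v_over_r = 1.915 [1.422, 2.408]
#>   q_over_r = 0.08249 [-0.02475, 0.1897]
#>   delta_x = 0.03867 [0.02849, 0.04885]

loo_timeseries(rnd, window_k = 11)
#> <model_selection> window k = 11, chosen: two_state
#>    static iterative two_state
#>  11062.02  12331.09  10826.02

pred <- predict_condition(fit$params, wlk)
sprintf("observed walk c = %.3f; predicted c = %.3f",
        central_tendency(wlk), pred$metrics$c)
#> "observed walk c = 0.000; predicted c = 0.015"
```

Reading the output: this simulated observer compresses the randomized
session (`c = 0.27`) and shows a small positive serial dependence
(`s = 0.028`); the fitted ratios recover the generating truth
(`v/r = 2.03`, `q/r = 0.16`) within their 95% intervals; windowed LOO
prefers the two-state model over both nested alternatives; and the same
parameters, applied unchanged to the random-walk ordering, predict the
near-disappearance of the central tendency that the simulated data indeed
show.

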