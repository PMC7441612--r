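# recruitcast

Recruitment trajectory analysis and Bayesian accrual prediction for
randomized controlled trials.

Slow patient recruitment is the most common reason randomized trials are
discontinued, and trial teams, funders and ethics committees all face the
same questions at interim monitoring points: how long will recruitment
take, and what is the risk that the trial finishes late or never reaches
its target? `recruitcast` is aimed at trial statisticians and
methodologists studying recruitment across portfolios of multicenter
RCTs. It provides:

- **Data model and descriptives** — ingestion of patient-level
  randomization dates, site activation records and trial metadata from
  delimited text; recruitment trajectories (cumulative accrual as a
  proportion of target); completion classification by the 90% rule (80%
  sensitivity variant); seasonal profiles; early-slope associations; the
  classical accrual-pattern checks.
- **Prediction** — a conjugate Bayesian accrual model and a
  constant-rate frequentist comparator, with posterior-predictive
  intervals, the risk of late completion, and a site-activation-aware
  variant for multicenter trials.
- **Simulation** — a multicenter recruitment generator (per-site Poisson
  processes, staggered activation, gamma rate heterogeneity, optional
  seasonality, discontinuation rules) for methods evaluation.
- **Validation** — a landmark engine that scores every model at time-
  and proportion-based interim landmarks with percent relative bias,
  interval coverage and P_late calibration.

## The model

Waiting times between successive randomizations are modelled as i.i.d.
exponential with unknown mean θ (months per patient). With an
inverse-gamma prior

θ ~ IG(shape = P·n, scale = P·T),

where *n* is the planned sample size, *T* the anticipated recruitment
time and *P* ∈ [0, 1] a prior confidence weight (the fraction of the
planned trial the prior evidence is worth), observing *m* patients in
*t* months gives the conjugate posterior

θ | data ~ IG(P·n + m, P·T + t).

*P* = 0 is the scale-invariant non-informative limit (proper once
*m* ≥ 1). The time to recruit the remaining *n* − *m* patients is a
gamma sum of exponential waiting times, so the predicted completion time
T_pred is simulated by drawing θ from the posterior and then the gamma
remainder (50,000 draws by default). Summaries are the predictive median
with an equal-tailed 95% interval, plus

- **P_late = Pr(T_pred > T | data)** — the estimated risk of accrual
  failure, the fraction of predictive draws beyond the anticipated
  completion date, and
- a **slow-accrual flag**: anticipated *T* strictly below the lower
  interval bound.

The comparator assumes a constant rate, estimates it as *m*/*t*, and
propagates the exact (Garwood) Poisson rate interval to completion time.
Model accuracy is scored as %Rbias = |Predicted − True| / True × 100.

## Worked example

A trial planned for *n* = 200 patients over *T* = 24 months has
randomized 50 patients after 8 months:

```r
library(recruitcast)

prior   <- accrual_prior(n = 200, T = 24, P = 0.5)
interim <- interim_state(m = 50, t = 8, n = 200)
post    <- fit_posterior(prior, interim)
post
#> <posterior_state> theta ~ inverse-gamma(shape = 150.000, scale = 20.000); m = 50, t = 8.000 months
#>   posterior mean waiting time: 0.1342 months/patient

pred <- predict_completion_time(post, remaining = interim$remaining, seed = 1)
pred
#> <prediction_result> completion_time: 28.00 months, 95% interval (23.96, 33.10)
p_late(post, interim$remaining, T = 24, seed = 1)
#> [1] 0.97342
flag_slow_accrual(pred, 24)
#> [1] FALSE

linear_predict(interim, n = 200)
#> <prediction_result> completion_time: 32.00 months, 95% interval (24.27, 43.11)
```

The posterior blends the prior rate (200/24 ≈ 8.3 patients/month) with
the slower observed rate (6.25/month): recruitment is predicted to take
28 months (95% interval 24.0–33.1), a 97% risk of finishing later than
planned — a clear signal to act — though the anticipated time is not yet
below the interval's lower bound, so the hard slow-accrual flag stays
off. The constant-rate extrapolation, which ignores the prior, is more
pessimistic and far less precise.

On a simulated portfolio the landmark validation engine compares the
models across interim landmarks:

```r
sim  <- simulate_portfolio(simulation_config(n_trials = 30, seed = 1))
rows <- landmark_validate(sim$portfolio, draws = 5000, seed = 1)
compare_models(rows)[1:4, c("landmark", "n", "median_rbias_a",
                            "median_rbias_b", "frac_a_lower")]
#>      landmark  n median_rbias_a median_rbias_b frac_a_lower
#> 1 10% accrual 30           6.18          30.03        0.933
#> 2 20% accrual 30           6.59          14.37        0.900
#> 3 30% accrual 30           7.81          13.69        0.833
#> 4 40% accrual 30           5.21           8.95        0.800
```

Early in recruitment the informative Bayesian model (column `a`) halves
or better the median %Rbias of the linear comparator (column `b`); the
advantage narrows as accrual data accumulate.

`coverage_summary()`, `p_late_calibration()`, `pattern_report()`,
`seasonal_profile()` and the plotting helpers complete the analysis; a
thin command-line wrapper with `simulate`, `describe`, `predict`,
`validate` and `report` subcommands lives at `inst/cli/recruitcast`.

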