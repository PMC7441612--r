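---
title: "Methods: recruitment modelling, simulation and landmark validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recruitment modelling, simulation and landmark validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recruitcast)
```

This vignette is the package's own account of its methods: the accrual
model and its assumptions, the choices made where the design was
genuinely open, what the simulator does and does not emulate, and the
numerical conventions that make results reproducible.

## The accrual model

`recruitcast` treats recruitment as a renewal process with i.i.d.
exponential waiting times between randomizations, mean θ in months per
patient — equivalently, a homogeneous Poisson process at rate 1/θ. This
is the standard constant-rate Bayesian accrual formulation: it takes as
input exactly what a trial team has at the planning stage (planned size
$n$, anticipated time $T$) and at a monitoring point ($m$ patients by
time $t$), and returns a predicted completion time with an interval.

The prior is inverse-gamma,

$$\theta \sim \mathrm{IG}(\text{shape} = P n,\ \text{scale} = P T),$$

so its mean is roughly the planned pace $T/n$ and the weight $P$ has a
direct reading: the prior carries as much information as a fraction $P$
of the planned trial. Exponential likelihood then gives the conjugate
posterior $\mathrm{IG}(Pn + m,\ PT + t)$. The non-informative analysis
is the limit $P \to 0$, the scale-invariant prior $\propto 1/\theta$,
whose posterior $\mathrm{IG}(m, t)$ is proper once $m \ge 1$; the
package refuses to form it at $m = 0$ rather than return an improper
object.

Two hyperparameterization choices deserve note, since accrual software
in this family does not always print its equations:

* $P$ scales **both** the shape (through $Pn$) and the scale (through
  $PT$). This keeps the prior mean at the planned pace regardless of
  $P$ and makes prior and data exchangeable pseudo-observations.
* When site activation dates are modelled (`predict_with_sites()`),
  exposure is re-expressed in *site-months* — the summed active time of
  all sites — and θ becomes the mean waiting time per site-month. The
  posterior is $\mathrm{IG}(Pn + m,\ P S_{\text{planned}} + s_{\text{obs}})$
  with $S$ the site-month analogue of $T$; predictive draws of the
  required future exposure are mapped back to calendar time through the
  piecewise-linear future activation schedule. When every site is active
  from day one this reduces exactly to the pooled model with $t$ and $T$
  multiplied by the site count (a unit change, not a different model).

### Prediction and its summaries

Completion-time prediction is direct Monte Carlo: draw θ from the
posterior, then the time to recruit the remaining $n - m$ patients as a
$\mathrm{Gamma}(n-m, \theta)$ sum. No Markov chain is involved — the
posterior is conjugate, so chains would add autocorrelation without
benefit — but the conventional draw count of 50,000 is kept as the
default. Accrual-count prediction over a horizon draws a Poisson count
at rate $1/\theta$, which marginally is over-dispersed relative to any
fixed-rate Poisson (rate uncertainty adds variance); a test asserts this.

The point estimate is the predictive **median**: the completion-time
distribution mixes a gamma with an inverse-gamma and has a heavy right
tail, so the median is the stabler summary (the mean is also reported
and is what the closed form $t + (n-m)\,\text{scale}/(\text{shape}-1)$
checks). Intervals are equal-tailed at level 0.95 by default. `P_late`
is the fraction of predictive draws beyond the anticipated time $T$, and
the slow-accrual flag uses a **strict** inequality ($T$ strictly below
the lower bound): at the boundary the evidence does not separate the
trial from its plan, so the flag stays off.

The frequentist comparator assumes a constant rate, estimates it as
$m/t$, and converts the exact Garwood Poisson interval for the rate into
a completion-time interval (lower rate bound → upper time bound). It is
deliberately the textbook method a coordinating centre would apply with
a spreadsheet.

## Conventions for time and landmarks

* Months are fixed at 365.25/12 = 30.4375 days everywhere; mixing
  calendar months with day arithmetic is a classic source of
  irreproducibility.
* The time origin is the date of first randomization (an
  activation-date origin is available by flag where activation is
  recorded).
* Time-based landmarks count events with day offset **strictly less**
  than the landmark in days — a half-open window $[0, t)$ — so a
  landmark never conditions on an event exactly at its own boundary.
  Proportion-based landmarks use `ceiling(fraction * target)` and take
  the first offset reaching it.
* Dates are ISO-8601 only; same-day randomizations collapse into one
  step of the corresponding height, with no intra-day ordering assumed.

## Completion classification

A trial with a stated discontinuation reason keeps it. Otherwise the
trial is "discontinued, unknown reason" when achieved accrual falls
below 90% of the reference size, and completed otherwise. Two points
were genuinely open:

* **Reference size.** Published definitions oscillate between the
  statistical sample size and the (often inflated) recruitment target.
  The package uses the statistical sample size when recorded and falls
  back to the recruitment target — the statistical size is the
  scientifically meaningful denominator, the target the operational one.
* **The 80% sensitivity rule** is phrased "80% or less", so it is
  implemented inclusively (`inclusive = TRUE`), while the primary 90%
  rule is strict. Both are arguments, not constants.

In landmark validation the primary analysis set contains completed
trials and those discontinued for poor recruitment; the "unknown"
category is included with them because that label is assigned precisely
by the below-threshold rule — it *is* poor recruitment without a
paper trail. Trials stopped for benefit, harm, futility, external
evidence or administration enter only a flagged sensitivity run, and a
test asserts the sensitivity run reproduces the primary rows unchanged.

## Validation targets

"True" recruitment time is the time to the last randomized patient, and
predictions at a landmark target the trial's **achieved final count**
rather than its never-necessarily-reached target. For completed trials
the two coincide; for discontinued trials this is the only definition
under which "the actual recruitment time" exists at all. A consequence
worth knowing: the linear model at the final landmark has %Rbias 0 by
construction, and the validation engine skips landmarks at which
recruitment had already finished (prediction there is hindsight).
Skipped (trial, landmark, model) combinations are tallied on the result.
Per-row Monte-Carlo seeds are derived from the run seed and the row's
stable coordinates (trial row, landmark, model), so adding models or
sensitivity trials to a run never changes another row's draws.

## The simulator and what it stands for

No patient-level multi-trial recruitment database is publicly deposited,
so the package ships a generator with the statistical structure the
analyses assume, standing in for a portfolio of several hundred RCTs.
Each site recruits as a Poisson process from its activation time; the
defaults were chosen once as a realistic mid-size portfolio and are not
tuned to any real data source:

| parameter | default | reading |
|---|---|---|
| statistical sample size | lognormal, median 150, sdlog 0.5, floor 20 | mid-size phase-III-ish trials |
| target inflation | 1.10 | targets modestly above the statistical size |
| sites per trial | 1 + Poisson(3) | small multicenter trials |
| per-site rate | Gamma(shape 2), mean 1.5 patients/site/month | strong cross-site heterogeneity |
| activation lags | Exponential, mean 2 months | staggered start-up |
| seasonal amplitude | 0 (configurable < 1) | seasonality off unless studied |
| cutoff | 0.6 × rate-implied duration, on 15% of trials | induces poor-recruitment discontinuations |
| origins | uniform 2015–2019 | identifiable calendar seasonality |

Seasonality is implemented by exact thinning of a dominating homogeneous
process with acceptance probability proportional to
$1 + A\cos(2\pi(\text{cal} - \text{phase})/12)$ — exact, and with a
closed-form oracle for tests. Per-trial seeds are a documented
multiplicative hash of (portfolio seed, trial index), so portfolios
reproduce exactly and trials are mutually independent streams. Event
times are generated in continuous time and serialized as dates at day
resolution; the continuous times are retained in the truth object for
distributional tests.

What the generator does **not** emulate: consent refusal and screening
funnels, informative site closure, rate drift within a site (beyond
seasonality), competition between trials, and country-level structure.
Passing calibration tests on this generator therefore shows the
machinery is correct *under its own assumptions* — the well-specified
case — not that real portfolios satisfy those assumptions. The
prior-consistent generator (`simulate_prior_consistent_portfolio()`,
`calibration_experiment()`) is deliberately matched to the model: it
answers "is the posterior arithmetic and interval construction right?",
the necessary condition any implementation must meet before
misspecification can even be studied.

## Numerical choices and problem sizes

* Inverse-gamma draws are `scale / rgamma(n, shape)`; gamma sums use
  `rgamma(n, shape = remaining) * theta` — vectorized, no loops over
  draws.
* Grid oracles in the test suite integrate on the log-θ scale with the
  Jacobian, 20–40k trapezoid points, placed ±12–14 posterior SDs around
  the mode; the conjugate posterior mean must agree to relative error
  below 10⁻⁴.
* The seasonal permutation test rotates each trial's calendar anchor
  over the 12 month offsets and uses a chi-square-style discrepancy;
  p-values use the add-one convention $(1 + \#\{ \ge \})/(B + 1)$.
* Bootstrap intervals are percentile with 1000 resamples, seeded.
* "Marked acceleration" of accrual — a pattern check with no agreed
  definition in the literature — is operationalized as: fitted slope of
  monthly counts positive and exceeding twice its standard error, *and*
  month-13-onward mean rate above 1.5× the months-1–3 mean. This is a
  declared choice; under constant-rate generation it flags essentially
  nothing, which is the behaviour the check exists to detect departures
  from.
* Experiment sizes in the shipped tests: calibration at 500 trials ×
  10,000 draws, parameter recovery at 200 replicates of 150
  observations, model comparison at 100 portfolio replicates of 15
  trials, simulator fidelity at 200 replicates; the standalone
  calibration script uses 1000 trials × 50,000 draws. These sizes give
  Monte-Carlo error comfortably inside each check's tolerance.

## Known limitations

* The constant-rate assumption is the model, not a belief about trials:
  ramp-up beyond site staggering, secular drift, and event-driven
  (time-to-event) accrual are out of scope.
* The package validates predictions against realized recruitment; it
  does not model *why* recruitment fails, and associations in the
  pattern report are descriptive, not causal.
* Hierarchical borrowing across trials in a portfolio (a natural next
  step for the prior) is not implemented.
* Count-prediction validation uses the anticipated time as the horizon
  when available and the realized end otherwise; with neither, count
  checks are skipped.
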