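---
title: "Validating time-to-event predictions: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating time-to-event predictions: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tteval)
```

## The validation problem

A deterministic mechanistic model of disease progression — for instance a
tumor-growth model run over a large virtual population — produces one exact
predicted time-to-event (PTTE) per virtual patient. The clinical data it must
be judged against are different in two fundamental ways. First, the observed
cohort is small (tens of patients, not tens of thousands), so naively testing
the full simulated population against the cohort gives statistical tests
essentially unlimited power: any negligible discrepancy becomes "significant".
Second, a clinical event is only discovered at the next scheduled visit, so a
reported time-to-event (RTTE) overestimates the true time by up to one
inter-visit delay. We call that delay the observation time uncertainty (OTU):
if visits are two months apart, the true event happened somewhere in the two
months before the reported date.

`tteval` implements six empirical validation metrics that address both
problems. All six are percentages in $[0, 100]$, compared against a common
acceptance threshold (80% by default), and they are computed together by
`tte_validate()`:

* **Raw coverage** — the share of the observation window where the observed
  Kaplan–Meier (KM) curve lies inside the bootstrapped 95% prediction
  interval of the simulated curve.
* **Juncture** — the share of the window where that prediction interval and
  the *observation variability band* (between the reported KM curve and the
  curve with all events shifted one OTU earlier) overlap at all.
* **Bootstrapped log-rank**, without and with OTU — the share of bootstrap
  iterations in which a two-sample log-rank test fails to reject equality.
* **Bootstrapped MaxCombo**, without and with OTU — the same with a
  combination of Fleming–Harrington weighted log-rank tests that keeps power
  under non-proportional hazards.

## Bootstrap construction

Both the prediction interval and the test-based metrics rest on the same
resampling idea: at each of $n$ iterations a subsample of the simulated pool,
of the same size as the observed cohort, is drawn (without replacement by
default — a sample *taken from* the set; with a pool several orders larger
than the cohort the distinction is negligible). For the prediction interval,
each subsample's KM curve is evaluated on a time grid and the pointwise
empirical 2.5% and 97.5% quantiles across iterations form the band. For the
test-based metrics, each subsample is tested against the observed cohort and
the fraction of non-significant tests at level $\alpha$ is reported; because
each comparison involves only a cohort-sized subsample, the test's power
stays at the level of the clinical study being mimicked.

The defaults follow the documented operating conditions throughout the
package: cohort-sized subsamples, $n = 5000$ iterations, $\alpha = 0.05$, an
80% acceptance threshold, and a 2-month OTU. A master seed spawns one
sub-seed per iteration before any iteration runs, and the pool subsample is
drawn before the OTU shift inside an iteration; two runs with the same master
seed therefore share their subsample draws whether or not OTU is switched on,
which makes with/without-OTU comparisons paired at no extra cost, and any run
is bit-reproducible from its seed.

## The weighted log-rank family and MaxCombo

The two-sample statistic accumulates, over the distinct pooled event times
$t_i$ with $d_i$ pooled events, $n_i$ subjects at risk and $d_{1i}, n_{1i}$
the event/at-risk counts of the first group,

$$U = \sum_i w_i \left( d_{1i} - d_i \frac{n_{1i}}{n_i} \right), \qquad
  V = \sum_i w_i^2\, d_i \frac{n_{1i}}{n_i}
      \left(1 - \frac{n_{1i}}{n_i}\right) \frac{n_i - d_i}{n_i - 1},$$

with $z = U/\sqrt{V}$ referred to the standard normal. The weights are the
Fleming–Harrington family $w_i = \hat S(t_i^-)^{\rho} (1 - \hat
S(t_i^-))^{\gamma}$, with $\hat S$ the *pooled* KM estimate taken at the left
limit — the standard evaluation point for this family. FH(0,0) is the
classical log-rank; FH(1,0) up-weights early event times, FH(1,1) the middle
of follow-up, FH(0,1) late times. MaxCombo runs all four, keeps the one with
the largest $|z|$ (ties resolved to the first in that listed order, which
only matters in degenerate all-zero cases), and multiplies its p-value by 4
(Bonferroni). Three conventions are deliberate and documented rather than
inherited: p-values are two-sided (the validation question is "different or
not", not directional), selection uses $|z|$ consistently with that
two-sided framing, and the Bonferroni factor is the literal 4 even though
the four statistics are highly correlated — making the combination
conservative rather than anti-conservative.

At each bootstrap iteration a proportional-hazards diagnostic is run on the
same pair, for exploratory purposes: a Cox regression on the group indicator
followed by the scaled-Schoenfeld-residual score test (`survival::cox.zph`).
A high violation ratio warns that the plain log-rank metric is operating
outside its comfort zone and more weight should be given to MaxCombo.
Degenerate fits (a group with fewer than two events) are reported as "not
evaluable" rather than as violations, and iterations whose test itself fails
are excluded from the metric's denominator — counting them as non-significant
would inflate the validation ratio.

## The observation-time-uncertainty model

Two distinct uses of the OTU width $\Delta$:

* **Deterministic band (juncture).** Every *event* time is shifted to
  $\max(0, t - \Delta)$ and the KM curve is refitted; the band between the
  reported and shifted curves is the region where the true event-free curve
  could plausibly lie. Censored records are not shifted here: censoring is an
  administrative boundary, not an observed event. One consequence worth
  knowing: with censored records interleaved, the refitted shifted curve is
  not always below the reported one (a censoring falling between an event's
  shifted and original positions changes the risk sets), so the band is
  defined as the pointwise min/max envelope of the two curves. For
  event-only data the shift is a pure left translation and the shifted curve
  is exactly the lower edge.
* **Random shifts (test variants).** Each patient receives an independent
  draw $u \sim \mathrm{Uniform}(-\Delta, 0)$ added to their time, redrawn at
  every bootstrap iteration. Here *all* records are shifted — the draw is
  assigned to the patient, not to the event. Shifted times are clipped at
  zero and the clip count is retained.

The band is treated as uniform-plausibility: the juncture metric asks only
whether the band and the prediction interval share any value at a time
point, without weighting positions inside the band, since nothing in the
observation process says where in the inter-visit gap the event occurred.

## Grids, boundaries and numerical conventions

* **Midpoint grid.** Interval metrics are computed on the midpoints of 1000
  equal cells spanning $[0, T_{end}]$ (`time_grid()`). Count-of-grid-points
  estimators then agree *exactly* with the length-based definitions for any
  union of sub-intervals aligned to cell boundaries, reconciling the two
  natural readings (fraction of time points vs fraction of window length)
  of both interval metrics. A coverage transition inside a cell is resolved
  at the cell's midpoint, so the discretization error is bounded by half a
  cell width per transition.
* **Window.** $T_{end}$ is the smaller of the observed maximum follow-up and
  the largest simulated time, so no extrapolated observed values enter the
  metrics; `evaluate_km()` flags extrapolation whenever a caller does probe
  beyond follow-up.
* **Closed comparisons everywhere.** Touching a prediction-interval bound
  counts as covered, a shared single value counts as overlap, and a metric
  exactly at the threshold validates. These boundary conventions are
  internally consistent: juncture can then never fall below raw coverage,
  because the reported curve is one edge of the observation band.
* **KM conventions.** Ties between events and censorings resolve
  events-first; curves are right-continuous (the drop occurs at the event
  time); the product-limit fit itself is delegated to `survival::survfit`.
* **Degenerate variance.** Risk sets of size one contribute zero variance;
  a fully degenerate $V = 0$ yields $z = 0$, $p = 1$ with a warning rather
  than an error, so bootstrap loops survive pathological subsamples.
* **Quantiles.** Pointwise interval bounds use the default continuous sample
  quantile; since every bootstrap curve is non-increasing, the bounds are
  automatically non-increasing, and the constructor enforces this.

## The synthetic-data generator

`simulate_model_pool()` emulates a deterministic model's output: exact event
times (every record an event), optionally with a unit-mean log-normal frailty
multiplying each virtual patient's hazard to mimic parameter variability
across the virtual population. `simulate_trial()` emulates the clinical side:
true times from a parametric hazard, exponential censoring sized so the
marginal censoring probability equals the requested rate, and visit-schedule
reporting — an event is reported at the first multiple of the visit interval
at or after its true time, so reported minus true always lies in
$[0, \Delta)$, which is the defining contract of the observation model.
Censoring times pass through unrounded (administrative dates are known
exactly). The visit grid is anchored at zero with equal spacing.

The five presets are sized like a targeted-therapy cohort: 74 patients,
2-month visits, 10% censoring, a 0.08/month baseline hazard (median around
8.7 months). `null` uses the same exponential for pool and trial; `shifted`
delays trial events by a gross 3 months; `early_difference` halves the trial
hazard before month 6; `late_difference` halves it after month 6 (a delayed
treatment effect); `crossing` opposes two piecewise hazards (0.05 then 0.20
per month at month 8, and the reverse) so the curves cross and proportional
hazards fails. What the generator does *not* emulate: patient covariates,
per-patient visit calendars, informative censoring or observation processes,
and treatment switching. Passing tests therefore demonstrate correctness of
the metrics under clean, independent-censoring conditions, not robustness to
those real-data complications.

## TTP derivation from PFS and OS

When the model predicts time-to-progression but the published curves are
progression-free and overall survival, TTP events are recovered by dropping
censored PFS records and removing PFS events that match an OS event within a
small tolerance (default 2 days, converted at 30.4375 days/month) — those
are deaths before progression, under the assumption that such deaths carry
identical times in both lists. The matching discipline is deliberately
deterministic: PFS events in ascending order, each matched one-to-one to the
closest unused OS event in tolerance, distance ties to the earliest OS time;
multi-candidate cases are counted as ambiguous in the report. Censored
removal precedes death matching. Two honest caveats: coincidental
within-tolerance matches can remove a genuine progression (the tolerance is
a trade-off against digitization error, and the report's pair list makes
every removal auditable), and removing deaths does not shift the KM curve in
one guaranteed direction — an early removed event raises the later curve —
so directional statements about the derived curve are empirical, not
structural.

## Calibration and power: what is conditional, what is marginal

A subtlety that shapes how the package's own checks are designed. For one
*fixed* observed cohort, the ratio of significant bootstrap tests is a
conditional quantity: under the null it varies widely from cohort draw to
cohort draw (the cohort contributes about half the variance of the
statistic, and conditioning on it shifts the rejection rate anywhere from
well below to well above $\alpha$). The $\alpha$-level statement — about 5%
of tests significant when the model is correct — holds *marginally*, over
fresh cohort draws. The package's calibration checks therefore re-draw the
cohort for every test, and users should read a single run's ratio as a
property of their particular cohort, not as an estimate of $\alpha$. The
same logic applies to power comparisons between MaxCombo and the plain
log-rank: orderings conditional on one simulated cohort are unstable, so the
package's power-ordering check is marginal and paired (both tests see the
identical subsample/cohort pair in each replicate). That check also uses the
scenario's exact event times: visit-schedule rounding superimposes a
$+\mathrm{U}[0, \Delta)$ location shift on every event, a model-misfit
signal in its own right that the unweighted log-rank picks up efficiently
and that would otherwise mask the late-difference contrast the check is
about.

## Problem sizes used by the checks

The package's test suite and the reproduction script run at the documented
operating conditions where the quantity demands it — $10^5$-endpoint pools,
74-patient cohorts, 5000 bootstrap iterations for the null-scenario
validation and the size calibration, 2000 paired replicates for the power
ordering — and at reduced sizes (hundreds of iterations, pools of a few
thousand) for structural and invariant checks where the assertion does not
depend on Monte-Carlo resolution.

## Known limitations

* The log-rank normal approximation is slightly liberal at cohort sizes
  around 74 per arm (the same behaviour is visible in
  `survival::survdiff`); the calibration check budgets for this within its
  Monte-Carlo band.
* Interval metrics depend strongly on the width of the prediction interval:
  a model with inflated variability earns high coverage cheaply. The
  test-based metrics are the intended counterweight; report all six.
* Only right censoring, two groups, and unstratified comparisons are
  supported; there is no interval-censored likelihood (the OTU band is a
  bounding construction, not a Turnbull estimator).
* The Bonferroni factor of 4 makes MaxCombo conservative under proportional
  hazards, where the plain log-rank is the more sensitive instrument.

## A minimal session

```{r example, eval = FALSE}
pool <- simulate_model_pool(1e5, event_dist("exponential", rate = 0.08))
trial <- simulate_trial(scenario_presets()$null)
v <- tte_validate(pool, trial$reported, otu_width = 2, n_iter = 5000, seed = 1)
print(v)
plot(v)
write_validation_json(v, "report.json")
```
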