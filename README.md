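# tteval — empirical validation of time-to-event model predictions

Deterministic mechanistic models of disease progression (for example
tumor-growth models in quantitative systems pharmacology) output one exact
predicted time-to-event per virtual patient, for as many virtual patients as
one cares to simulate. Deciding whether such a model is *validated* against
a small observed clinical cohort raises two problems that standard survival
testing does not handle well: a test applied to the whole virtual population
has essentially unlimited power, so it flags negligible discrepancies; and
observed event times are only known up to the clinic's visit schedule — an
event is reported at the visit where it is discovered, up to one inter-visit
delay after it truly happened (the *observation time uncertainty*, OTU).

`tteval` is for modellers and biostatisticians who need a quantitative,
reproducible answer. It implements six validation metrics, all percentages
compared against a common acceptance threshold (80% by default):

| Metric | Idea |
|---|---|
| Raw coverage | % of the window where the observed Kaplan–Meier curve lies inside the bootstrapped 95% prediction interval of the simulated curve |
| Juncture | % of the window where that interval and the OTU observation band overlap at all |
| Bootstrapped log-rank (±OTU) | % of bootstrap iterations where a cohort-sized simulated subsample is *not* significantly different from the cohort |
| Bootstrapped MaxCombo (±OTU) | the same with Fleming–Harrington weighted log-ranks combined, robust to non-proportional hazards |

The core two-sample statistic is the weighted log-rank
*z* = *U*/√*V* with

```
U = Σ_i w_i (d_1i − d_i n_1i / n_i)
V = Σ_i w_i² d_i (n_1i/n_i)(1 − n_1i/n_i)(n_i − d_i)/(n_i − 1)
w_i = Ŝ(t_i⁻)^ρ (1 − Ŝ(t_i⁻))^γ        (Fleming–Harrington FH(ρ, γ))
```

summed over pooled event times; MaxCombo runs FH(0,0), FH(1,0), FH(1,1),
FH(0,1), keeps the largest |z| and Bonferroni-corrects its p-value.
Bootstrapping with cohort-sized subsamples keeps the power of every
comparison at the level of the clinical study being mimicked. A
proportional-hazards diagnostic (scaled Schoenfeld residuals) runs at each
iteration so users can judge when the plain log-rank is trustworthy.

The package also ships a synthetic clinical-trial simulator with known
ground truth (visit-schedule reporting guarantees `reported − true ∈
[0, Δ)`), and a preprocessor deriving time-to-progression event lists from
digitized PFS and OS curves by removing censored records and
death-before-progression events (2-day matching tolerance).

## Worked example

Validate a correct model: a 20 000-endpoint exponential pool against a
74-patient trial simulated from the same distribution, observed with
2-month visits and 10% censoring.

```r
library(tteval)
set.seed(1)
pool  <- simulate_model_pool(2e4, event_dist("exponential", rate = 0.08))
trial <- simulate_trial(scenario_presets()$null)
v <- tte_validate(pool, trial$reported, otu_width = 2, n_iter = 500, seed = 42)
print(v)
```

```
Time-to-event model validation
  pool: 20000 simulated endpoints; observed: 74 records (69 events)
  OTU 2 months, 500 iterations, alpha 0.05, threshold 80%

  Raw coverage                         96.40%  validated
  Juncture                            100.00%  validated
  Bootstrapped log-rank (no OTU)       99.00%  validated  (PH violated 2.00%)
  Bootstrapped log-rank (with OTU)     99.00%  validated  (PH violated 2.40%)
  Bootstrapped MaxCombo (no OTU)       99.60%  validated  (PH violated 1.00%)
  Bootstrapped MaxCombo (with OTU)     99.80%  validated  (PH violated 1.20%)

  overall: 6 of 6 methods validated
```

Read this as: the observed curve sits inside the model's 95% prediction
interval over 96.4% of the follow-up window; the OTU band and the interval
always share values; and at least 99% of cohort-sized statistical
comparisons find no significant difference — every metric clears the 80%
threshold, so the model validates on all six methods. `plot(v)` draws the
observed curve over the green prediction band;
`write_validation_json(v, "report.json")` emits the machine-readable
report. A misspecified model (try `scenario_presets()$shifted`) drives the
test-based metrics toward 0%. `exec/tteval.R` wraps the same functions as
`validate` / `simulate` / `preprocess` / `compare` shell subcommands.

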