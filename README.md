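# clockbind

Estimation of the **action-binding effect** from a modified Libet-clock
experiment, and of its relation to **delusional ideation**, for
researchers working on intentional binding and the sense of agency.

In the task, a clock hand rotates once every 1800 ms and the participant
tries to press a key exactly when the hand passes the 12 o'clock
position, then judges whether the press was *before*, *at*, or *after*
that position.  Each condition runs until 40 trials judged "at 12" have
been acquired.  In the baseline condition the press has no consequence
(**AO**, action only); in the operant condition it triggers a tone 250 ms
later (**AS**, action + sound).  On an at-12 trial the reported press
position is the 12 o'clock crossing, so with `t1` the physical press
time and `t2` the crossing time,

- perceived keypress time = `t2 − t1` (positive → awareness later than
  the press),
- actual keypress time = `t1 − t2` (negative → pressed early).

**Action binding** is the shift of the perceived press toward the delayed
tone: per participant, the AS median minus the AO median of the
perceived keypress times (or, as a precision-weighted *binding
strength*, the trial-level unpaired t statistic of AS vs AO).  The
pipeline implements:

- **MAD-median participant exclusion** on the average perceived keypress
  time `p`: flag when `|p − median(P)| · 0.6745 > 3 · MAD`;
- group contrasts with **Cohen's effect sizes** `dz = t/√n` (paired) and
  `ds = t·√(1/n₁ + 1/n₂)` (unpaired, pooled design);
- the **testing-order (carryover) effect**: OLS slopes of perceived time
  over at-12 trials, and a **leave-first-n-trials-out scan** that drops
  the first n = 0, 1, 2, … at-12 trials of each condition, recomputes the
  between-order-group binding contrast, and reports the cut-off n* from
  which the contrast stays non-significant;
- **PDI-21 scoring** (21 yes/no items, each endorsed item adds
  1 + distress + preoccupation + conviction on 1–5 scales; range 0–336)
  and the one-tailed **Pearson correlation** between PDI overall score
  and binding strength, with boxplot-rule (1.5 IQR) exclusion and a
  seeded percentile-bootstrap 95% CI;
- a **synthetic-cohort generator** that reproduces the task's statistical
  structure (per-participant shifts, truncated aiming noise calibrated to
  ~41 ms per-condition SD, acquisition-until-40-at-12, exponentially
  decaying carryover, a latent delusional trait coupled to the binding
  increment) together with a ground-truth ledger, so the whole pipeline
  is validated by parameter recovery.

See `vignettes/clockbind-methods.Rmd` for the generative model, its
parameters and the design choices.

## Worked example

```r
library(clockbind)

cohort <- simulate_cohort(sim_config(seed = 20260301))
bundle <- run_pipeline(cohort$trials, cohort$pdi, seed = 20260301)
print(bundle)
```

```
Action-binding analysis bundle
  AO condition: mean perceived keypress time 32.57 ms (95% CI [24.82 40.32], n = 52)
  AS condition: mean perceived keypress time 56.37 ms (95% CI [48.17 64.57], n = 52)
  action binding (AS - AO): 23.80 ms, t(51) = 11.52, p = 4.14e-16, one-tailed, dz = 1.60
  order-group contrast on binding: t(50) = 0.03, p = 0.98, two-tailed, ds = 0.01
  excluded by MAD-median rule: 0 of 52
  order effect non-significant from 0 dropped trials on (alpha = 0.05)
  PDI vs binding strength: r = 0.01, p = 0.472, one-tailed, 95% CI [-0.29 0.34], n = 49 (52 - 0 incomplete - 3 boxplot)
```

Reading the output: the perceived keypress time is ~24 ms later in the
AS condition — the action-binding effect (the generator's true increment
is 23 ms).  The two testing-order groups do not differ here because this
cohort's carryover, after taking medians over 40 trials, shifts the
group means by only a few ms.  The correlation line shows the full
exclusion accounting; note that a single cohort of ~49 usable pairs
estimates a correlation with a standard error of about 0.14, so
individual cohorts scatter widely around the generating value — the
test suite checks the mean over 200 cohorts instead.

## Analysis workflow

The `analysis/` scripts run the same stages as a narrative, reading and
writing files under `results/`:

```sh
Rscript analysis/01_simulate.R      # cohort CSVs + ground truth
Rscript analysis/02_validity.R     # before/at/after judgement validity
Rscript analysis/03_binding.R      # exclusions, condition means, contrasts
Rscript analysis/04_order_scan.R   # slopes, leave-first-n scan, cut-off
Rscript analysis/05_correlation.R  # PDI vs binding strength
```

Real data exported in the same CSV dialects (see `?read_trials`,
`?read_pdi`) can be analysed by pointing the scripts, or
`run_pipeline()`, at those files.

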