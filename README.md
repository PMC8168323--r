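# survrecon

Reconstruct individual patient data (IPD) from published Kaplan-Meier
survival curves.

Secondary analyses of time-to-event outcomes — meta-analysis, landmark
survival, non-proportional-hazards checks, subgroup work — want one record
per patient (time, event indicator, arm). Published trials usually provide
only a Kaplan-Meier plot with a number-at-risk table beneath it. `survrecon`
is for biostatisticians and evidence-synthesis researchers who need to turn
that published summary back into analyzable IPD.

## What it does

Given coordinates digitized off a published K-M curve (any plot digitizer,
or `calibrate_pixels()` for raw pixel clicks) plus the risk table
`(trisk_i, nrisk_i)`:

1. **Preprocess** (`preprocess_curve()`): stable sort, percent-axis
   detection, Tukey's fence (k = 3) on the successive survival increments
   to drop extraction blunders, forced monotonicity (running minimum), step
   control (each vertical drop reduced to its top and bottom point so its
   event count is rounded once), and partition of the points into the
   risk-table intervals.
2. **Reconstruct** (`reconstruct_ipd()`): interval-by-interval inversion of
   the product-limit estimator
   `S(t_q) = Π (1 − d_j/n_j)`, `n_{q+1} = n_q − d_q − c_q`.
   Each interval's censoring total starts at
   `round(nrisk_i · S_{lower_{i+1}}/S_{lower_i}) − nrisk_{i+1}` and is
   refined until the implied at-risk count matches the published
   `nrisk_{i+1}`, under the box constraint
   `0 ≤ ncensor_i ≤ nrisk_i − nrisk_{i+1}` that keeps every event,
   censoring and at-risk estimate non-negative. Events sit at the curve's
   drop times; censorings are spread evenly within their interval.
3. **Assess** (`accuracy_summary()`, `nrisk_recovery()`): RMSE, mean and
   max absolute error of survival probabilities at the read-in times
   (rule-of-thumb thresholds 0.05 / 0.02 / 0.05), a Kolmogorov-Smirnov
   comparison, and reported-vs-estimated numbers at risk.
4. **Analyze** (`survreport()`, `km_fit()`, `logrank_test()`,
   `hazard_ratio()`, `bootstrap_hr_ci()`): landmark survival with Greenwood
   SEs and log(−log) CIs, survival quantiles, log-rank test, Efron-tie Cox
   hazard ratios with Wald and bootstrap intervals.
5. **Validate** (`simulate_trial()`, `simulate_km_arm()`, `sim_grid()`): a
   Weibull trial simulator (staggered accrual, calibrated dropout,
   administrative censoring, risk tables every 3 or 10 months) provides
   ground truth for the whole pipeline.

A command-line wrapper is installed at `inst/cli/survrecon` with
subcommands `preprocess`, `reconstruct`, `assess`, `survreport`,
`simulate`, `pixels2data`.

## Worked example

```r
library(survrecon)
sim  <- simulate_km_arm(n = 200, mean = 12, shape = 1,
                        target_censor = 0.30, risk_every = 3, seed = 1)
prep <- preprocess_curve(sim$points, trisk = sim$trisk, nrisk = sim$nrisk)
rec  <- reconstruct_ipd(prep, arm = "treat")
summary(rec)
```

```
Accuracy of reconstruction:
  RMSE           0.0026 (threshold 0.05)
  mean |error|   0.0013 (threshold 0.02)
  max |error|    0.0288 (threshold 0.05)
  K-S statistic  0.0236 (p = 1.000)
Number at risk, reported vs estimated:
 trisk reported estimated error
     0      200       200     0
     3      139       139     0
     6      100       100     0
   ...
```

The simulated arm (200 patients, exponential events with a 12-month mean,
30% censoring) is digitized exactly, reconstructed, and compared with its
own coordinates: all error summaries sit far below the thresholds, the
number at risk is recovered exactly at every report time, and the
reconstructed median survival (7.71 months) matches the true-IPD median
(7.63 months) to about 1%.

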