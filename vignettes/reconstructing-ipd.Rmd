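---
title: "Reconstructing individual patient data from published Kaplan-Meier curves"
author: "survrecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing individual patient data from published Kaplan-Meier curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survrecon)
```

## The problem

Meta-analyses and other secondary analyses of time-to-event outcomes are
best done on individual patient data (IPD): one record per patient with an
observed time, an event indicator, and an arm label. Published trials,
however, usually report only a Kaplan-Meier (K-M) plot with a
number-at-risk table printed beneath it. `survrecon` inverts that summary:
given coordinates digitized off the published curve and the number-at-risk
table, it reconstructs an IPD table whose K-M curve reproduces the
published one, quantifies how well it does so, and runs standard secondary
analyses (landmark survival, survival quantiles, log-rank test, hazard
ratios with bootstrap confidence intervals) on the result.

## The reconstruction model

The K-M estimator at the $q$-th distinct event time is the product of
conditional survival factors

$$ \hat S(t_q) = \prod_{j \le q} \left(1 - \frac{d_j}{n_j}\right), \qquad
   n_{q+1} = n_q - d_q - c_q, $$

with $n_q$ patients at risk, $d_q$ events and $c_q$ censorings between
event times. Digitized coordinates $(T_k, S_k)$ sample this step function;
the published risk table $(trisk_i, nrisk_i)$ pins down $n$ at the
interval starts. Reconstruction inverts the product limit interval by
interval:

1. **Initial censoring total** for interval $i$:
   $\widehat{ncensor}_i = \mathrm{round}(nrisk_i \cdot
   S_{lower_{i+1}}/S_{lower_i}) - nrisk_{i+1}$, clamped into
   $[0,\, nrisk_i - nrisk_{i+1}]$.
2. **Censor placement**: assuming a constant censoring rate inside the
   interval, the $\widehat{ncensor}_i$ censorings sit at equally spaced
   interior times; each coordinate $k$ receives the censorings whose times
   fall in $[T_k, T_{k+1})$.
3. **Sweep**: walking the interval's coordinates,
   $\hat d_k = \mathrm{round}\!\left(\hat n_k (1 - S_k/\hat
   S^{KM}_{last(k)})\right)$ clamped to $[0, \hat n_k]$, where
   $\hat S^{KM}_{last(k)}$ is the running estimate at the last coordinate
   that carried an event (the curve is flat in between); then
   $\hat n_{k+1} = \hat n_k - \hat d_k - \widehat{cens}_k$.
4. **Refinement**: if the implied at-risk count at the next report time
   misses $nrisk_{i+1}$, the censoring total is shifted by the signed
   discrepancy and the sweep repeats -- but only while the total can move
   without leaving $[0, nrisk_i - nrisk_{i+1}]$. This box constraint is
   what keeps every estimate non-negative; an unconstrained version of the
   same update can walk the censoring total below zero on dense risk
   tables (the package's tests construct such a case).
5. **Last interval**: no report time closes it, so its censoring total is
   seeded with $\min(\text{average censoring rate} \times \text{interval
   length},\ nrisk_I - endpts - (tot.events - \sum \hat d_k))$, clamped
   non-negative, where the average rate is total censoring so far divided
   by elapsed time, `endpts` is the number still at risk at the end of the
   curve (default 0), and the second term degenerates to
   $nrisk_I - endpts$ without a reported event total.

Events are emitted at the drop times of the digitized curve; censored
patients carry their placed times; patients still at risk after the last
interval are censored at the final coordinate. The reconstruction
therefore conserves the starting cohort exactly:
$\sum \hat d + \sum \widehat{cens} + \hat n_{final} = nrisk_1$.

## Preprocessing digitized coordinates

Manual extraction produces unsorted, slightly non-monotone points with the
occasional blunder. `preprocess_curve()` applies, in order:

* **Sorting and scale detection.** Points are stably sorted by time; a
  curve whose maximum survival exceeds 1.5 is treated as percent-scaled
  and divided by 100 (fractions never exceed 1, percent axes start well
  above it). An anchor $(trisk_1, 1)$ is prepended when the digitized
  curve does not start at full survival, so the first product-limit factor
  is defined.
* **Tukey's fence** with multiplier $k = 3$ on the successive survival
  increments $S_k - S_{k-1}$: genuine geometry yields zeros and modest
  drops, extraction blunders yield anomalous jumps. The quantity fenced is
  a package choice -- increments localize a blunder to a single point --
  and $k = 3$ is deliberately loose so that real points survive. A small
  absolute slack ($10^{-8}$) keeps a degenerate zero-IQR fence from
  flagging floating-point noise.
* **Force monotonicity**: survival is replaced by its running minimum.
  Unlike deleting offending points this keeps the point count, and unlike
  isotonic regression it cannot smooth a sharp step away.
* **Step control**: each run of points sharing one time (a vertical drop)
  is reduced to its top and bottom point, so a drop's event count is
  rounded once. Rounding each sub-point separately can round a genuine
  drop down to zero events when many sub-points are digitized.
* **Interval partition**: coordinates are assigned to half-open windows
  $[trisk_i, trisk_{i+1})$, the last window closed at the final
  coordinate; a boundary point belongs to the later interval because
  `nrisk` counts patients at risk at the *beginning* of an interval.
  Windows containing no point are merged into their predecessor with a
  warning. Without a risk table, a single interval is built from the
  supplied total sample size -- reconstruction then has no interior
  anchor and is correspondingly less accurate.

## Numerical choices

* All count roundings use round-half-away-from-zero, fixed for
  reproducibility across platforms.
* Censoring inside an interval keeps its computed placement time, so
  reconstructed censor times are non-tied, as the constant-rate
  assumption implies.
* The censoring refinement is capped at 10,000 passes per interval; the
  box constraints guarantee termination well before that on sane inputs,
  and the best iterate (smallest at-risk discrepancy) is kept if a cycle
  is detected. On small intervals the refinement provably lands on the
  brute-force minimizer of the discrepancy (tested by enumeration).
* Whether the initial censoring guess is clamped before or after the
  first sweep is underdetermined; it is clamped before.
* In the accuracy assessment, a read-in point followed by another at the
  same time is the top of a vertical drop; it is compared against the
  left limit of the reconstructed curve, the bottom against the step
  value. Pairing both with the right-continuous value would charge a
  perfect reconstruction with residuals equal to its own drop sizes.

## Accuracy assessment

`accuracy_summary()` evaluates the reconstructed curve at every read-in
time and reports RMSE, mean and maximum absolute error of the survival
probabilities, plus a two-sample Kolmogorov-Smirnov comparison of the
read-in and estimated survival values (the construction of the KS
comparison is a package choice; the test is advisory given the heavy
ties). The thresholds RMSE $\le 0.05$, mean $\le 0.02$ and max $\le 0.05$
are a rule of thumb for "well captured"; they are surfaced as warnings,
never errors. `nrisk_recovery()` tabulates estimated minus reported
numbers at risk per report time.

## The trial simulator

Because real digitized curves come with no ground truth, the package
ships a simulator that emulates a two-arm randomized trial: per patient,
entry uniform over a 36-month accrual window, Weibull event time with
survival $S(t) = e^{-(t/b)^\gamma}$ scaled so the mean is 12 months
(treatment) or 6 months (control), exponential dropout, and
administrative censoring at study end (36 + 24 months after the first
entry, i.e. per-patient horizons between 24 and 60 months -- measuring
follow-up from entry is the only reading that makes a 24-month follow-up
compatible with risk tables extending towards 60 months). The dropout
rate is calibrated by bisection, on a fixed set of Monte-Carlo draws so
the censoring fraction is monotone in the rate, until dropout plus
administrative censoring hits the 30% or 60% target within ±0.5%. The
number-at-risk table is reported every 3 months (20 report times over the
60-month horizon) or every 10 (6 report times), or withheld.

The Weibull mean is taken as $b\,\Gamma(1+1/\gamma)$ with
$\lambda = b^{-\gamma}$; a mean written directly as
$\lambda\Gamma(1+1/\gamma)$ would be dimensionally inconsistent with
$S(t)=e^{-\lambda t^\gamma}$.

Exported "digitized" coordinates are exact: the origin, both the top and
bottom point of every drop (the recommended extraction practice), a point
at every risk-report time, and the final point of the curve. Gaussian
jitter (`digitization_noise()`) can be layered on to emulate manual
extraction error. What the simulator does *not* emulate: pixel
quantization, curve-crossing confusion between arms, informative or
covariate-dependent censoring, and reporting granularity of the published
axes. Passing the round-trip tests therefore shows the inversion is
faithful to the published summary, not that any real digitization is
error-free.

`sim_grid()` fixes six trial configurations spanning decreasing
($\gamma = 0.8$), constant ($\gamma = 1$) and increasing ($\gamma = 1.5$)
hazards at 30% and 60% censoring, with one null trial (equal 12-month
means) so that both rejection and non-rejection of the log-rank null are
exercised; all use 200 patients per arm and a 3-month risk table. The
test suite and the acceptance script run at these sizes: one arm
reconstructs in well under a second, so the full grid stays in the
seconds range.

## A worked run

```{r example}
sim <- simulate_km_arm(n = 200, mean = 12, shape = 1,
                       target_censor = 0.30, risk_every = 3, seed = 1)
prep <- preprocess_curve(sim$points, trisk = sim$trisk, nrisk = sim$nrisk)
rec <- reconstruct_ipd(prep, arm = "treat")
summary(rec)
```

```{r secondary}
trial <- simulate_trial(sim_config(seed = 2))
rec_t <- reconstruct_ipd(preprocess_curve(trial$arms$treat$points,
                                          trisk = trial$arms$treat$trisk,
                                          nrisk = trial$arms$treat$nrisk),
                         arm = "treat")
rec_c <- reconstruct_ipd(preprocess_curve(trial$arms$ctrl$points,
                                          trisk = trial$arms$ctrl$trisk,
                                          nrisk = trial$arms$ctrl$nrisk),
                         arm = "ctrl")
survreport(rec_t$ipd, rec_c$ipd, s = c(0.5, 0.75))
```

## Known limitations

* The censoring model inside an interval is uniform; trials with strongly
  non-uniform dropout will be reconstructed with the right totals but
  distorted censor times.
* Without a number-at-risk table the censoring structure is essentially
  unidentified: the package then attributes censoring to the curve tail
  (or to the reported event total when given), which recovers the curve
  but not the censoring pattern.
* Reconstructed patients are not independent draws from the underlying
  survival law -- standard errors from secondary analyses treat them as
  if they were, which is the usual caveat of curve-reconstruction
  methods; the bootstrap interval quantifies, but does not remove, this.
* The hazard-ratio partial likelihood uses Efron tie handling; with the
  heavy event ties of reconstructed IPD other tie conventions shift the
  estimate slightly.
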