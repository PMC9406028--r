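---
title: "Activity-based 30-day readmission prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity-based 30-day readmission prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pareadmit)
```

## The problem

Patients with chronic obstructive pulmonary disease (COPD) have the highest
30-day hospital readmission burden of any major disease group, and their
physical activity (PA) of daily living is a strong correlate of health
status and exacerbation risk. `pareadmit` implements a pipeline that turns
continuous wrist-accelerometer recordings into daily activity features,
frames readmission prediction as a sliding-window classification problem,
and evaluates the resulting classifier from two complementary points of
view: per-window prediction accuracy and per-event precision.

Because clinical accelerometer cohorts are not openly shareable, the
package ships a synthetic-cohort generator that reproduces the statistical
structure the analysis depends on; every stage of the pipeline is exercised
and tested against it.

## Activity features

The raw signal is a tri-axial acceleration series $(a_{x,i}, a_{y,i},
a_{z,i})$ in g-units. Per sample the *resultant acceleration* is the
Euclidean norm $A_i = \sqrt{a_{x,i}^2 + a_{y,i}^2 + a_{z,i}^2}$. The day is
cut into 5-second *epochs* of $N$ samples ($N = 100$ at the default 20 Hz
sampling rate), and within each epoch

$$\mu = \frac{1}{N}\sum_i A_i, \qquad
  \sigma_k = \sqrt{\frac{1}{N}\sum_i (A_i - \mu)^2}.$$

The divisor is $N$ (population SD), deliberately: the SD removes the
constant 1 g gravity component, so $\sigma_k$ quantifies actual movement
within the epoch regardless of wrist orientation. The minute-level
*Activity Index* is the sum of the 12 epoch SDs in that minute,
$\mathrm{AI}_m = \sum_{k=1}^{12} \sigma_k$; the *hourly PA* is the sum of
the 60 minute AIs of a clock hour. The *Regularity Index* of day $d$ is the
Pearson correlation between the 24-vector of hourly PA of day $d-1$ and
that of day $d$, a measure of routine stability. The daily *Quality of
Activity* blends volume and regularity:
$\mathrm{QoA}_d = \left(\sum_{m=1}^{1440}\mathrm{AI}_m\right)(1 +
\mathrm{RI}_d) \ge 0$.

Epochs, minutes and hours are anchored to the 00:00 wall-clock boundaries
of the UTC day, since the minute index runs 1..1440 over a 24-h day. A day
enters the analysis only when at least 16 h of data were recorded in it;
"continuous" is implemented as *cumulative* coverage by default, with an
optional cap on the largest single internal gap (`max_gap_hours`) for
stricter readings.

Decisions where the method description is genuinely open:

* **Undefined RI** (first observed day, neighbour day not wear-valid, or a
  zero-variance hourly pattern): RI is stored as `NA`; QoA substitutes a
  regularity-neutral RI of 0, so QoA degrades to the plain daily AI sum
  rather than being invented or dropped.
* **Missing data** are absent, never zero: empty epochs and minutes are
  excluded from sums, and a per-day `wear_seconds` is kept so downstream
  filtering stays possible.

## Windows, labels and features

A *dataset* in this analysis is a window of 7 consecutive wear-valid days;
windows slide by one day, so consecutive windows overlap by 6 days. The
prediction attached to a window refers to the day after its last day. A
window is *valid* only when hospital follow-up covers the 30 days after
its last day — otherwise its prediction could not be adjudicated — and a
valid window is *positive* when a readmission falls in
`(last_day, last_day + 30]`: an event on the last recorded day is not a
future readmission, while one exactly 30 days out still counts. Windows
whose span contains a readmission date are excluded so that in-hospital
days never feed the at-home activity model.

The 48-dimensional feature vector uses only quantities defined above: for
each of the 7 days `(ai_sum, ai_mean, ai_median, ai_cov, ri, qoa)` (42
values, RI -> 0 when undefined), plus six cross-window aggregates — mean
and CoV of the daily AI sums, mean RI, mean QoA, and the least-squares
trend slopes of the daily AI sum and of QoA. The slopes are the one
engineered addition: a readmission is typically preceded by a progressive
activity decline, which a within-window trend captures directly.
Standardization is always computed from training folds only.

## Classifier and cross-validation

The classifier is logistic regression trained from scratch with per-example
stochastic gradient descent on the log-loss:
$\hat y = \sigma(w \cdot x + b)$ with
$w_i \leftarrow w_i - \alpha(\hat y - y)x_i$ and
$b \leftarrow b - \alpha(\hat y - y)$. Weights start from seeded
$\mathcal N(0, 0.01^2)$ values, examples are reshuffled each epoch, and
training stops at `n_epochs` (default 200) or when the epoch-mean log-loss
improves by less than `tol` (default 1e-6). The learning rate default is
0.01 — stable on standardized features; the decision threshold is 0.5,
inclusive, and both live in `run_config()`, not in code. The SGD step is
verified against a numerical log-loss gradient, and the estimator against
`glm()` maximum-likelihood fits on synthetic logistic data — `glm` is the
cross-check, never the implementation.

Overlapping windows make ordinary k-fold CV leak: a day can appear in both
a training and a test window. `split_folds()` therefore performs *blocked*
cross-validation: windows are grouped into time blocks that share no
calendar day (blocks are separated by at least 7 days of last-day distance,
i.e. a 6-day guard gap — the minimum making 7-day windows disjoint), blocks
are dealt to the k folds in seeded random order, and windows falling inside
a guard gap are excluded. Leakage-freedom is asserted by exhaustive
day-set intersection in the tests.

The final model is the element-wise average of the per-fold weights and
biases, with a pooled standardization over all cross-validated rows. An
averaged model is one defensible reading of "final validated model taken as
the average"; averaging in standardized space is coherent here because the
per-fold standardizations are computed from 90% subsamples of the same data
and so nearly coincide. A full-data refit is the obvious alternative and is
a one-line change; the averaged model is the default because it is what the
evaluation statistics below were designed around.

## Dual evaluation

* **Prediction-based**: each valid window's prediction is adjudicated
  individually; accuracy $= 100\cdot TP/(TP+FP)$ over predicted windows,
  with the false-prediction rate its exact complement.
* **Event-based**: each actual readmission is truly predicted (TE) when at
  least one window predicted a readmission in the 30 days *prior* —
  predicting-window last days in `[event - 30, event - 1]`; a prediction
  dated the event day itself is not prior. Precision
  $= 100\cdot TE/(TE+ME)$.

Worked example, which is also the package's acceptance anchor: with 1361
valid windows, 199 predictions of which TP = 140 and FP = 59, accuracy is
70.35% and the false-prediction rate 29.65%; with 21 events of which
TE = 15 and ME = 6, event precision is 71.43% and the missed-event rate
28.57%. Undefined ratios (zero denominator) are reported as `NA`, never as
0 or 100. Percentages are stored at full precision and printed to two
decimals.

Because predictions near one event are highly correlated (30 chances per
event), event-based precision needs a calibrated reference:
`permutation_null_precision()` permutes the predicted flags across valid
windows, giving the precision distribution under prediction–event
independence at the observed prediction rate. A classifier carries signal
when its observed precision exceeds the null's upper tail.

## The synthetic cohort

`cohort_config()` defaults define the study conditions: 16 patients
observed 243 days each (3888 patient-days, matching the ~3900-day scale of
the motivating cohort), 20 Hz sampling (100 samples per 5 s epoch), a
two-state circadian template (00:00–06:00 night at 0.01 g resting jitter;
06:00–24:00 daytime with Poisson bouts at 2/h, 10 min long, 0.08 g — light
wrist activity), non-wear gaps (0.3/day, 6 h, emitted as absent rows so the
16-h rule has something real to reject), and readmissions scheduled with a
0.0055/day hazard and a 30-day refractory period, which yields about 20
events per cohort. Before each event, bout amplitude ramps linearly from 1
at `event - decline_days` to `decline_floor` on the event day (defaults: 10
days, 0.5). The decline is multiplicative on bout amplitude, not on the
gravity baseline, precisely so that the SD-based features respond to it.

Raw 20 Hz generation at cohort scale would mean ~7 billion samples, so the
generator has two output levels sharing one per-minute activity/wear/event
schedule. `output = "raw"` expands the schedule into tri-axial samples
(gravity along z plus per-axis noise at the minute's activity SD) and is
used wherever the per-sample formulas are under test. `output = "daily"`
draws each wear minute's AI directly from the sampling distribution the raw
model implies — the epoch's population SD is distributed as
$s\sqrt{\chi^2_{N-1}/N}$, and the minute AI is a 12-fold sum of those,
approximated by a zero-truncated normal with the exact mean and variance.
Both levels produce identical event logs for identical seeds, and their
daily AI sums agree to a few percent on shared schedules (a tested
property).

What the generator does *not* emulate: posture and gait physiology,
device/firmware artifacts beyond gap insertion, between-patient
heterogeneity in baseline activity, seasonal trends, and unrecorded
interventions that prevent readmissions. Passing tests therefore
demonstrate the pipeline's correctness and its ability to detect a
decline-type signal under realistic noise, wear gaps and label dilution —
not clinical performance on real patients, where declines can be abrupt
rather than gradual and baselines vary.

## Problem sizes and determinism

The test suite runs the full pipeline on the default 16-patient cohort
(~3000 windows, 10 folds) for the signal-detection property, a 50-patient
cohort for the decline construction, and 20 replicate fits at n = 2000 for
parameter recovery; these sizes give stable statistics while keeping the
suite fast. Every random draw is seeded: identical configurations produce
byte-identical CSV/JSON artifacts end to end, which the tests assert at the
byte level.

The pipeline is exposed as R functions (`run_config()`, `run_pipeline()`,
and the per-stage functions they compose) rather than a shell subcommand
tool — users of an analysis package drive it from R; `scripts/acceptance.R`
is a worked example of scripting it non-interactively.

## Known limitations

* The RI of day *d* uses the pair (*d-1*, *d*); smoothed or multi-day
  regularity variants are not implemented.
* Class imbalance handling is available (`class_weights`) but off by
  default; with the default threshold the classifier is conservative,
  predicting only clearly declining windows.
* Event-based precision ignores how *early* an event was flagged beyond
  the 30-day rule; no lead-time analysis is provided.
* Calendar handling assumes UTC day boundaries; local-time and DST
  handling is the caller's responsibility when importing real recordings.
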