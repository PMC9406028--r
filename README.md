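# pareadmit

Activity-based 30-day hospital readmission prediction from wrist
accelerometry, for researchers studying COPD and other chronic conditions
where physical activity (PA) of daily living tracks health status.

Patients with COPD lead all major disease groups in 30-day readmissions,
and their daily activity declines ahead of many exacerbations. `pareadmit`
turns continuous tri-axial wrist-accelerometer recordings into daily
activity features, frames readmission prediction as a sliding-window
classification problem, and evaluates the classifier both per prediction
and per event:

* **Features** — per-sample resultant acceleration
  `A = sqrt(ax^2 + ay^2 + az^2)`; per-5-second-epoch population SD
  `sigma_k` (removes the constant gravity component); minute **Activity
  Index** `AI = sum of 12 epoch SDs`; **Regularity Index** `RI =
  cor(hourly PA of day d-1, day d)`; daily **Quality of Activity**
  `QoA = (sum of minute AI) * (1 + RI)`; and a 16-hour/day wear-validity
  rule.
* **Windows** — overlapping 7-day windows of wear-valid days, labelled
  positive when a readmission falls within the 30 days after the window's
  last day, valid only when 30 days of follow-up exist to adjudicate them.
* **Model** — logistic regression trained from scratch by per-example SGD
  (`w_i <- w_i - alpha * (yhat - y) * x_i`), with *blocked* 10-fold
  cross-validation (no calendar day shared between folds) and an averaged
  final model.
* **Evaluation** — prediction-based accuracy `100 * TP / (TP + FP)` and
  event-based precision `100 * TE / (TE + ME)`, plus a permutation null
  for the event-based view.
* **Synthetic cohorts** — a generator with circadian structure, Poisson
  activity bouts, non-wear gaps and a configurable pre-readmission
  activity decline, so the whole pipeline is testable without clinical
  data.

## Worked example

```r
library(pareadmit)

# a 16-patient cohort, 243 days each, 10-day activity decline to 50%
# of bout amplitude before each scheduled readmission
cfg <- run_config(cohort = cohort_config(seed = 1))
res <- run_pipeline(cfg)
res$report
```

```
30-day readmission evaluation
  windows (total):      3067
  valid windows:        2679
  predicted windows:    121
  TP / FP:              120 / 1
  prediction accuracy:  99.17%
  false prediction:     0.83%
  events:               17
  TE / ME:              16 / 1
  event precision:      94.12%
  missed events:        5.88%
```

Reading this: of 3067 sliding 7-day windows, 2679 had 30 days of known
follow-up and could be adjudicated. The cross-validated model flagged 121
of them; 120 were indeed followed by a readmission within 30 days
(prediction-based accuracy 99.17%). Of the cohort's 17 readmissions, 16
had at least one flagged window in their preceding 30 days (event-based
precision 94.12%). The synthetic decline is deliberately clean; on real
patients, abrupt exacerbations and heterogeneous baselines make both
numbers substantially lower.

The feature primitives are exported individually:

```r
resultant_acceleration(0.6, 0.8, 1.0)  # 1.414214
epoch_stats(c(1, 3))$sigma             # 1  (population SD)
regularity_index(1:24, 24:1)           # -1
```

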