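---
title: "Simulating and detecting treatment intolerance in monitored oncology cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and detecting treatment intolerance in monitored oncology cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncotol)
```

## Scope and assumptions

`oncotol` models the analytics layer of a remote-monitoring system for
patients on Pembrolizumab plus chemotherapy: weekly binary
adverse-effect panels, rule-based detectors over wearable-style
signals, a 30-feature alerting model, and symptom co-occurrence
statistics. It deliberately does *not* model pharmacokinetics,
continuous CTCAE severity grades, device transport layers, or the
clinician annotation process — labels on synthetic data come from an
explicit, configurable rule (see below).

## The cohort simulator

Each patient-week-symptom probability is
`P_base(j) * F_sus(i) * M_temp(j,k)`, clamped to [0, 1].

* **`P_base`** — baseline weekly occurrence probabilities taken from
  published adverse-effect rates for the drug combination (e.g. nausea
  0.535, fatigue 0.585, insomnia 0.21). They are stored as fractions
  in `default_p_base()` and fully overridable.
* **`F_sus`** — a per-patient susceptibility factor, Gaussian
  (mean 1.0, sd 0.20) bounded to [0.5, 1.8]. The default sampler is a
  true truncated normal via inverse-CDF transform; each draw consumes
  exactly one uniform variate, which keeps the per-patient random
  substreams aligned. A `clip` option reproduces the alternative
  reading (clamping unbounded draws), at the cost of point masses at
  the bounds; truncation is the default precisely to avoid those
  masses.
* **`M_temp`** — week- and symptom-specific multipliers. No published
  values exist, so the default profile is all ones; a
  `cycle_ramp_modifiers()` example is shipped and clearly marked as
  illustrative only.
* **Correlation rules** — trigger→target tuples with an additive boost
  `b` applied to the target's probability within the week the trigger
  fires. Published sources name the correlated pairs but not `b`; the
  default is `b = 0.15` for all ten default rules, configurable per
  rule. The default sampling order places all triggers (fatigue,
  nausea, vomiting, diarrhea) before every target, because a boost can
  only act on symptoms drawn after its trigger; order-dependence is
  inherent to the sequential algorithm and is preserved, not hidden.
  Boosts reset each week: the weekly probabilities are rebuilt from
  the baseline model, so clamping and boosting never accumulate across
  weeks.

Randomness uses one root seed with per-patient substreams derived
arithmetically (`seed + 10007 * patient_index`), so enlarging the
cohort leaves earlier patients' trajectories untouched.

## The low-tolerance proxy label

Clinically, "low treatment tolerance" means the patient's state
warrants reassessment of the regimen — CTCAE grade ≥ 2 effects
requiring modification, dose reduction or delay, suspension, or
unplanned hospitalization. That judgment cannot be computed from a
binary panel, so synthetic cohorts are labeled by an explicit
surrogate (`label_rules()`), applied per patient-week:

1. ≥ `min_concurrent_symptoms` distinct symptoms this week (default 6);
2. any sentinel symptom present (default: none);
3. any sentinel combination fully present (defaults: the digestive
   triad nausea+vomiting+diarrhea, and the cachexia-like pair
   fatigue+weight loss);
4. any single symptom active for ≥ `persistence_weeks` consecutive
   weeks (default 3).

The concurrency threshold was calibrated once against the only
available anchor for the label distribution — the ~63% positive
fraction reported for combined real-plus-synthetic monitoring
datasets. Under the default simulator the mean weekly symptom count is
around four, so lower thresholds (or single-symptom sentinels such as
pyrexia, whose weekly rate is ~25%) would label nearly every week
positive and make the classification task degenerate. With the
defaults the simulated positive fraction lands near 0.63. The label is
monotone by construction: adding a symptom can never turn a positive
week negative.

Because the label is a deterministic function of the panel (and the
panel history), the alerting models can in principle recover it
perfectly. Passing model-performance properties on this cohort
therefore demonstrates pipeline correctness — leakage-free splits,
faithful feature engineering, working training code — not clinical
performance; real labels carry noise and context the simulation does
not represent.

## Detectors and their thresholds

Published criteria often state bands; the defaults take the more
sensitive end of each band, the natural choice for a screening system
whose cost asymmetry favors recall:

| quantity | default | band / source rule |
|---|---|---|
| sleep duration drop | 20% below baseline | 20–30%, or < 6 h absolute |
| sleep efficiency drop | 10 points | 10–15, or < 85% absolute |
| deep/REM share drop | 15% | 15–20% (counted as one criterion) |
| weight loss (6 weeks) | 1.15% | 5%/26 wk rescaled linearly |
| weight loss, BMI < 20 | 0.5% | 2%/26 wk rescaled |
| blood pressure | 140/90 mmHg, both, ≥ 3 readings | "both exceed across multiple measurements" |
| fever, absolute | > 37.8 °C for ≥ 30 min | persistent exceedance |
| fever, relative | > 0.4 °C above nightly baseline for > 2 h | sustained skin-temperature rise |

Choices the published rules leave open, decided here:

* *"Multiple measurements"* for hypertension is quantified as 3 within
  the week — the smallest plural count robust to a single artifact.
  The "both systolic and diastolic" conjunction conflicts with the
  usual either/or clinical definition; it is implemented as stated,
  with a `logic = "either"` switch.
* *"Persistently exceeds"* 37.8 °C is quantified as ≥ 30 contiguous
  minutes, which rejects single-sample spikes at the 10-minute
  recording cadence. The nightly temperature baseline is the median of
  the first recorded night; runs are broken at recording gaps longer
  than 30 minutes so a fever episode cannot span separate nights.
* The weight baseline is the mean of the first two weekly readings
  (the first alone if only one exists). The deep/REM criterion counts
  as a single "stage fragmentation" item, so insomnia still requires
  two of three distinct criteria.
* The insomnia baseline is the first monitored week (seven nights),
  which is excluded from flagging.

## Signal fixtures

`synth_sleep_week()`, `synth_bp_week()`, `synth_weight_series()`,
`synth_temp_series()` and `synth_survey_week()` generate raw streams
consistent with a weekly flag vector. They are detection oracles, not
physiology: active weeks clear the relevant thresholds by a wide
margin (e.g. disturbed nights at ~4.5 h duration and ~64% efficiency;
hypertensive readings around 156/100 mmHg; 2.5% linear weight loss;
fever episodes at 38.4 °C for 90 min or baseline + 0.8 °C for 3.5 h),
inactive weeks stay well inside, and small Gaussian noise (duration
0.25 h, BP 4/3 mmHg, weight 0.1 kg, skin temperature 0.1 °C) is added
on top. The margins are sized so that the matching detector recovers
the generating flag on ≥ 99% of seeded weeks; the residual allowance
covers rare noise coincidences (e.g. a noise dip splitting a
sustained-rise episode). No circadian structure, missingness, or
device artifacts are modeled — so detector performance on fixtures
says nothing about detector performance on real wearable data beyond
rule correctness.

## Feature engineering

The model input has exactly 30 columns: the 11 raw flags plus 19
engineered features — weekly symptom count, cumulative symptom load,
11 per-symptom consecutive-week durations, 3 interaction flags
(digestive, systemic, neurological), and three dynamics features
(previous-week count, week-over-week count change, longest
single-symptom streak to date). The published description enumerates
the first 16 engineered features by category but not the remaining
three; the final three are this package's reconstruction, chosen as
the simplest dynamics summaries consistent with the stated intent of
capturing temporal behavior. The builder takes a `manifest` argument
so alternative readings can be swapped in without touching code.

## Splitting, scaling, classifiers

The patient-wise split holds out 30% of patients (rounding half away
from zero), guaranteeing no patient appears on both sides — the
leakage mode that most inflates longitudinal clinical results. The
remaining patients' observations are split 80/20 into training and
validation at the observation level, matching the split sizes
672/168/360 for the default 200 × 6 cohort. Min-max scaling is fit on
training rows only; constant columns map to 0, and out-of-range values
on new data are left unclipped rather than silently truncated.

Four families are supported with fixed, seeded, single-threaded
defaults: logistic regression (`stats::glm`), radial SVM
(`e1071::svm`) whose decision margin is mapped to [0, 1] through a
monotone logistic link fitted on the training margins (so the decision
threshold `t_C` means the same thing across families), probability
random forest (`ranger`, 500 trees), and gradient boosting (`xgboost`,
150 rounds, depth 3, learning rate 0.1). No automated hyperparameter
search is performed by default: on the synthetic task the defaults
already saturate, and a search would only matter on real data where
validation-set selection belongs to the study design. Alerts use the
strict rule `score > t_C` (a score exactly at threshold does not
alert), and `threshold_sweep()` evaluates the 0.1–0.9 grid;
zero-denominator metrics are reported as `NA`, never as 0.

## Co-occurrence statistics

`phi_coefficient()` and `chi2_independence()` operate on 2×2
contingency tables of patient-week observations (the same denominators
as the prevalence figures); the identity χ² = n·φ² is maintained
exactly because the default test applies no continuity correction (a
Yates option exists). Degenerate tables — any zero marginal — return
`NA` rather than 0, since "no association" and "association undefined"
are different statements. Raw p-values at α = 0.05 are reported by
default, matching conventional per-pair screening; a Bonferroni
option is available. Note that patient-level susceptibility makes
symptoms positively dependent even with all boosts off — a shared
frailty effect — so null-calibration checks of the machinery must also
fix the susceptibility sd to zero.

## Problem sizes and numerical checks

The shipped tests run the simulator at up to 2,000 patients × 6 weeks
(12,000 patient-weeks) for prevalence recovery against a quadrature
oracle for the truncated-normal mean, 10,000 replicate weeks for the
boost arithmetic, 1,000 seeded fixture weeks per condition for
detector round-trips, and 200 null cohorts for type-I calibration of
the co-occurrence report. These sizes keep Monte-Carlo standard errors
small relative to the 3-standard-error acceptance bands while the full
suite completes in about a minute.

## Known limitations

* The proxy label is a rule, not a clinician: models trained on it
  learn the rule. Transfer to expert-labeled data is untested by
  construction.
* Binary flags discard severity; a CTCAE-graded simulation would
  change both the labeler and the feature set.
* Fixture signals are oracles with decisive margins; they cannot probe
  detector behavior near thresholds, which on real data is where
  errors live.
* The simulator's correlation structure is first-order
  (within-week, directed pairs); it does not generate longer-range
  symptom cascades or treatment-cycle dynamics unless `M_temp`
  profiles are supplied.
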