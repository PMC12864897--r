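---
title: "Methods: sepsis phenotyping and learning-health-system analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sepsis phenotyping and learning-health-system analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`slhs` implements the analytics of a hospital sepsis learning health
system: a registry of stays, ward segments, timestamped observations,
medications, clinician-adjudicated sepsis events, ICD-10 codes and
mortality outcomes goes in; per-stay sepsis classifications and
quality-of-care impact indicators come out. Because real sepsis registries
are not publicly shareable, the package ships a first-class synthetic
registry generator whose output exercises every downstream stage, and all
tests run on generated data. This vignette documents the models, the
tunable parameters, the numerical choices, and what the synthetic data do
and do not establish.

## The label model

Each adjudicated event carries one of six fine labels, in increasing
severity: no infection; infection without sepsis; sepsis-like (organ
failure with a SOFA increase below 2 points, or missing SOFA
information); sepsis sensu lato (a qualifying SOFA increase with an
alternative aetiology for the organ dysfunction); sepsis sensu stricto (a
qualifying increase with no alternative aetiology); septic shock (sensu
stricto plus vasopressor support plus serum lactate above 2.0 mmol/L).
The Sepsis-3 organ-dysfunction criterion is a delta-SOFA of at least 2
points: the maximum SOFA within 72 h after the annotated onset minus the
baseline SOFA over the 24 h before onset, with a zero baseline assumed
when no pre-onset assessment exists.

`classify_event()` maps a fact set — two clinician judgments (infection
present, alternative aetiology) plus facts computed from the data
(delta-SOFA, vasopressor administration, lactate above 2) — onto the six
labels deterministically, most severe applicable label first. The
"and/or" wording of the two possible-sepsis rows is resolved as: the
sepsis-like label covers infection with missing SOFA information or with
documented organ failure whose delta stays below 2; sensu lato requires a
qualifying delta *and* an alternative aetiology. This is the only reading
under which the sensu-stricto row's "no alternative aetiology" qualifier
partitions the delta >= 2 cases. Fact combinations that contradict each
other (organ failure attributed to infection without an infection; a
qualifying delta without documented organ failure) are rejected as
errors rather than silently classified. `collapse_label()` folds the six
labels onto the monitoring classes NS / PS / CS (no, possible, confirmed
sepsis).

Windows are labeled positively only when an event onset falls inside the
window's lookback span — the 7-day interval ending at the window's close.
Whether a window that overlaps only the aftermath of an event (onset
before the span) should count as positive is genuinely open; we require
the onset in the span, which matches the construction of both embedding
types. The label of a window with several qualifying events is the most
severe one.

## Clinical scores

SOFA uses the canonical six-organ banding (respiration PaO2/FiO2;
coagulation platelets; liver bilirubin; cardiovascular MAP/vasopressor;
CNS Glasgow Coma Scale; renal creatinine and optionally urine output),
each sub-score 0-4. Two registry-driven adaptations are documented
explicitly. First, the registry stores vasopressor *drug class* without
dose, so the dose-graded cardiovascular bands collapse to: any active
vasopressor maps to the low-dose band (sub-score 2); hypotension (MAP
below 70 mmHg) without vasopressors scores 1. A vasopressor
administration is considered active for 24 h. Second, the respiration
sub-scores 3 and 4 are assigned on the PaO2/FiO2 thresholds alone, since
the registry carries no ventilation flag. Missing organs score 0 with an
explicit imputation flag; an assessment with three or more absent organs
is treated as missing, and delta-SOFA requires at least one fresh
post-onset observation — carried-forward values alone never constitute an
assessment, so "no post-onset data" yields a missing marker, never zero.
These conventions feed the sepsis-like label's missing-SOFA pathway.

NEWS2 uses the canonical seven-component banding (respiratory rate, SpO2
scale 1, supplemental oxygen, temperature, systolic pressure, heart rate,
consciousness), total 0-20. The Charlson comorbidity index uses the
original 17-category weights with an ICD-10 prefix mapping shipped as an
editable fixture (`inst/extdata/charlson_icd10.csv`); hierarchical
exclusions (severe over mild liver disease, complicated over
uncomplicated diabetes, metastatic disease over other malignancy) are
applied, unknown codes are ignored.

## Windowing and features

Stays are cut into contiguous half-open 6-hour windows anchored at
admission (fragments of stays are stay-relative, not calendar-aligned);
6 h balances data completeness outside intensive care against compute.
Within a window each concept takes its last observed value; medications
are counted. Two representations feed the two sub-models:

* **Rolling aggregates** for the forest: each registered concept is
  aggregated over the 28-window (7-day) span ending at the target window,
  clipped at admission, with six aggregators: last, min, max, mean, count
  and the least-squares slope over window index. The deployed system's
  exact 240-feature list is unpublished; the default registry is a
  declarative concept-by-aggregator table of the same scale — 40 concepts
  (12 core physiologic channels plus 28 auxiliary laboratory channels)
  x 6 aggregators, plus age and sex, 242 features. Aggregates over empty
  spans stay NA and are median-imputed at training time with the
  imputation constants stored in the model bundle.

* **Sequence tensors** for the recurrent net: 28 right-aligned steps per
  target window, one channel per core concept plus a binary observed
  mask per channel. Values are forward-filled within the stay up to 48 h,
  then population-median imputed; pre-admission steps are zero-valued
  with mask 0. Masks are never altered by imputation, so the model can
  learn missingness patterns. Channels are z-scored with constants
  recorded at training time.

## The stacked classifier

Two heterogeneous sub-models classify every window into NS/PS/CS: a
random forest (ranger; 200 trees, depth cap 12, inverse-frequency class
weights) on the rolling aggregates, and a compact single-layer gated
recurrent network on the sequence tensors. No recurrent-network library
is part of the package's dependency set; the GRU is implemented directly
on matrix operations (minibatch Adam, class-weighted cross-entropy,
backpropagation through time) and its gradients are verified against
numerical differentiation in the test suite. Defaults are deliberately
small — hidden size 16, 12 epochs, learning rate 0.02 — and fully exposed
in `run_config()`. Because windows without events dominate (about 95% of
windows), the recurrent net trains on all positive windows plus a 5:1
subsampled negative background; the forest sees all windows.

The stacking layer is a second-stage random forest over exactly six
inputs: the two sub-models' three class probabilities each. To avoid
leakage the stacker is trained on *out-of-fold* sub-model probabilities
from a patient-grouped K-fold split (folds partition patients, never
splitting a patient's stays); the source system does not state this
construction, and we document it as a deviation by necessity — stacking
on in-fold probabilities would reward sub-model overfitting. Deployment
predictions average the fold sub-models (a cross-validation bag) before
stacking.

Per-window probabilities are aggregated to one value per stay by taking
the maximum confirmed-sepsis probability over the stay's windows; the
stay's 3-class label is the class of the window attaining that maximum,
ties resolved toward higher severity. The decision threshold tau is then
calibrated as the *largest* threshold whose induced confirmed-sepsis
recall on the training stays meets the configured floor (default 0.7).
The threshold applies per stay, matching the aggregate-then-flag reading
of the deployment; recall at tau on the training set is at least the
floor by construction, which is exactly the property the acceptance
suite asserts.

Model governance is champion-challenger: a retrained model is deployed
only if its selection metric strictly exceeds the incumbent's; ties keep
the champion. The deployed system's gate metric is unstated; the default
here is pooled confirmed-sepsis F1 (its headline internal metric), and
the metric is selectable. The deployed-metric sequence is therefore
non-decreasing over retraining rounds.

## Evaluation

Stay-level evaluation reports the 3x3 confusion matrix, one-vs-rest
precision/recall/F1 per class with explicit undefined flags on empty
denominators, unweighted macro-mean F1 (whether the headline F1 is
CS-only or macro is ambiguous, so both are reported), and two rank-based
AUROC contrasts with midrank tie handling: confirmed vs no sepsis
(possible-sepsis stays dropped) and confirmed-or-possible vs no sepsis.
Inter-rater agreement uses unweighted Cohen's kappa with the standard
large-sample Wald interval.

## Impact analysis

Stays are partitioned by ward exposure: stays *limited to* program wards
(every segment in MED/GIS/EMD), stays *including* program wards (at
least one segment), and control stays (all segments in control groups).
Indicators per cohort-year: percentage of sepsis-coded stays, percentage
of flagged stays (maximum windowed confirmed-sepsis probability above
the calibrated threshold — the only threshold the system defines), and
in-hospital / 30-day / 90-day mortality among flagged and unflagged
stays, with empty denominators reported as explicitly undefined. 90-day
mortality is measured from admission; post-discharge deaths require a
death timestamp.

Yearly trends are estimated by maximum-likelihood logistic regression on
year of admission, sex, age and Charlson index; the reported odds ratio
is the exponentiated year coefficient with a Wald 95% interval. Year
enters as a single continuous covariate — one odds ratio per panel
implies one coefficient — with a categorical-year variant selectable.
Whether the source analyses pooled cohorts in one regression or fitted
per-cohort regressions is unstated; we fit per cohort. Non-convergence
and separation are flagged, never silently reported.

Time-to-antibiotics compares order-set (pathway) events against
consult-identified controls: 1:1 nearest-neighbour matching without
replacement on the logit propensity score from age, sex and Charlson,
caliper 0.2 SD of the score, pathway rows processed in decreasing score
order; then a chi-squared test on the 2x2 matched table of group by
antibiotics-within-threshold (1 h and 3 h). Antibiotics given at or
before onset count as timely (delay floored at zero — clinically
conservative); censored events count as not timely.

## The synthetic registry

The generator emulates the statistical structure the pipeline assumes,
with defaults defining the reference study conditions: 2000 stays (about
1.7 stays per patient) over a 2020-2024 calendar; log-normal length of
stay (median 5 days, truncated to 0.5-30); up to three ward segments per
stay with a configurable EMD-first fraction and a control/program/mixed
ward mix; 10% of stays carrying one adjudicated event with a label mix
matching the adjudicated case distribution (events roughly 22% no
sepsis, 33% possible, 45% confirmed); ICD sepsis-coding sensitivity
0.833 for confirmed sepsis and 0.355 for possible sepsis (the
under-coding the system is designed to surface); in-hospital mortality
from a logistic model with a per-year odds ratio of 0.85, an age effect,
a confirmed-sepsis effect and an antibiotic-timeliness effect; and
onset-to-antibiotic delays exponential with mean 0.5 h for pathway
events versus 4 h for controls.

Physiology is simulated as patient-specific set-points plus observation
noise at concept-specific sampling intervals (vitals about 4 h,
laboratories about 24 h), which produces the realistic missingness the
imputation path needs. Sepsis episodes take a severity-scaled step at
onset with exponential recovery over 72 h. Injection is
label-consistent by construction: delta >= 2 labels receive explicit
post-onset organ-dysfunction laboratory values (platelets 80 x 10^9/L,
creatinine 250 umol/L) and the natural post-onset series is clamped so
carried-forward normal values cannot mask the dysfunction; delta < 2
labels have their post-onset score inputs clamped into normal bands with
a guaranteed valid assessment; the missing-SOFA variant removes the
stay's SOFA laboratory series; septic shock adds a vasopressor and a
lactate of 3.5 mmol/L, while all other labels cap post-onset lactate at
1.8 and carry no vasopressor. One event per stay is generated
(multi-event stays would let episode injections interfere within one
assessment window).

What the generator does *not* emulate: real between-ward case mix,
comorbidity-physiology correlation, seasonal and secular drift in
coding, informative (disease-driven) sampling frequency, and
inter-annotator disagreement. Green tests therefore establish that the
pipeline's logic is correct and its statistical machinery recovers known
generative parameters — not that the model reaches any particular
performance on real hospital data. The strong injected physiologic
signal makes the synthetic classification task much easier than the real
one; discrimination close to 1.0 on generated data is expected and is
used only as a sanity band.

## Problem sizes and numerical choices

The reference conditions (2000 stays, about 55,000 windows, 242
features, 5 folds) train in a few minutes on one core; the end-to-end
smoke test uses 500 stays. Rolling statistics are computed in one pass
over the 28 lags with stay-boundary masking; slopes need at least two
observations (else NA). Probability triples are normalized by
construction; stay aggregation and threshold calibration are exact
(sorting, not optimization). Determinism: one seed in `run_config()`
drives fold assignment, both sub-models and the stacker; the generator
is deterministic given its own seed; reports are byte-stable across
reruns.

## Known limitations

Retrospective, stay-level classification only — no real-time scoring and
no onset-time estimation, so time-to-antibiotics relies on annotated
onsets. The cardiovascular SOFA banding is coarsened by the
class-without-dose medication schema. The quasi-experimental impact
design inherits the usual caveats: control wards host different case
mixes, and the per-year odds ratio summarizes a trend, not a causal
effect.
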