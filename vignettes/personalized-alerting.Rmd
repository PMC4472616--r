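---
title: "Personalized alert thresholds for COPD telemonitoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized alert thresholds for COPD telemonitoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copdalert)
```

## The monitoring problem

Patients with COPD record three signals daily at home: a five-item symptom
diary (general well-being, cough, sputum quantity, sputum colour,
breathlessness; each item 0–4, total 0–20), pulse rate (beats/min) from a
pulse oximeter, and oxygen saturation (SpO2, %). Exacerbations are treated
by the patient with standby antibiotics and/or oral steroids, so the
medication diary doubles as the event record: an *exacerbation event* is a
medication day preceded by a drug-free gap.

Fixed alarm limits are a poor fit for this population: a patient can be
chronically stable at SpO2 levels that would be alarming for another. The
pipeline therefore fits one alerting rule per patient per signal.

## The alerting model

**Run-in.** Thresholds are estimated from an initial training window that
ends at the *earlier of* 42 calendar days and the day the 40th completed
diary is recorded (`run_in_spec()`). The "6 weeks or 40 diaries" phrasing is
ambiguous about which bound wins; the earlier-of rule caps both the
calendar exposure and the sample size, and the alternative (later-of) is a
one-line change to `run_in_spec()`. A patient needs at least `min_train =
10` non-missing values per signal, otherwise that signal is excluded with a
warning rather than fitted on noise.

**Distribution estimate.** The default estimator is the empirical CDF of
the training values with nearest-rank quantiles: assumption-free, exactly
testable against a counting oracle, and it always returns an observed
value. For an upper-tail signal the threshold is the smallest training
value whose CDF reaches `centile/100`; for SpO2 the rule is mirrored into
the lower tail at the same centile of the alerting direction (the 5th
percentile of the raw scale when `centile = 95`). A Gaussian-kernel CDF
(`method = "kernel"`, bandwidth `bw.nrd0`) is available for users who
prefer a smooth estimate that can fall between observations; the default
stays empirical because every downstream property can then be verified
exactly.

**Detection.** Every non-missing follow-up value is compared with the
threshold using *strict* inequality — "over the threshold" reads as beyond,
so a value exactly at the threshold does not alert. Run-in days never
alert. Thresholds are fitted once and never updated, matching a design in
which an initial training period defines the personal baseline.

**Monitoring flags.** Two operational rules are implemented as data checks:
a flag after a run of more than 7 consecutive non-completed days
(`flag_missing_gaps()`), and a contact flag when a patient is in the alert
zone on `k = 2` consecutive days (`flag_consecutive_alerts()`). The alert
zone is any-signal by default — the clinically conservative reading —
with a per-signal mode behind `by_signal = TRUE`.

## Event extraction and linkage

`extract_events()` starts an event at any medication day whose preceding
`merge_gap_days = 7` days are medication-free, and merges subsequent
medication days across gaps shorter than that, so a single skipped diary
inside a course does not split a treated exacerbation into two. Whether a
steroid course that immediately follows an antibiotic course is one event
or two is genuinely underdetermined; the merge gap is a parameter for
exactly that reason.

`link_alerts_to_events()` classifies each event independently: *preceded*
if any alert falls in the `window_days = 3` days strictly before the start
day ("prior" reads as strictly before; `include_event_day = TRUE` widens
the window by one). With zero events the proportion is reported as `NA`,
never 0.

False positives cannot be counted per alert day — a cohort can produce
hundreds of alert days but only a handful of spurious *episodes* — so
`cluster_alert_episodes()` groups alert days with gaps of at most
`fp_episode_gap_days = 3` into episodes, and an episode is a false positive
when no event starts inside it or within `window_days` after its last
day. False negatives are simply the non-preceded events, which keeps the
conservation identity `preceded + false negatives = events` exact by
construction (and property-tested).

Compliance is summarized per patient as the percentage of study days with
a completed record, plus the fraction of patients completing at least 5
days in every 7-day block from their day 0 (the final partial block is
prorated at the same 5/7 fraction). Weekly blocks are anchored at each
patient's start because no calendar-week convention is defined for this
kind of rolling enrolment.

## The synthetic cohort generator

No patient-level dataset exists to ship, so `simulate_cohort()` generates
one with the statistical structure the analysis assumes:

* **Baselines** per patient are uniform draws centred on the stable-period
  summary the generator emulates — symptom 9.6, pulse 83.4 beats/min, SpO2
  93.8% — with between-patient spreads and daily noise SDs that together
  give pooled SDs near 2.4 / 17 / 3.0 in the same units.
* **Daily noise** is stationary lag-1 autoregressive Gaussian
  (`autocorr` in [0, 1), default 0.2–0.5), the minimal model with realistic
  day-to-day persistence; the marginal SD equals the configured noise SD.
* **Exacerbation episodes** arrive as a Poisson count per patient (rate
  0.5–3.6 per 180 days, mean ≈ 2, matching roughly two self-treated
  episodes per patient per half year), with onsets resampled so episodes
  never overlap, keep a 14-day mutual gap, and avoid the first 42 days so
  the run-in mostly reflects the stable state. Each episode shifts the
  signals by its deltas, ramping *linearly* from zero at onset to the full
  delta at medication start (the simplest monotone prodrome, and the
  mechanism that makes "alert precedes medication" achievable at all),
  holding through the course, and reverting afterwards.
* **Missingness** is independent per-day Bernoulli (MCAR) at a per-patient
  compliance probability drawn from 0.40–0.98, the observed adherence
  range.
* The symptom score is ordinal: the latent Gaussian baseline is rounded to
  the 0–20 scale and split across the five items, so a noiseless patient's
  score is the rounded constant rather than the real-valued baseline. The
  two vitals are kept continuous.

What the generator does **not** emulate: informative (illness-driven)
missingness, seasonal or weather effects, instrument rounding, measurement
artefacts, or inter-signal correlation beyond the shared episode shifts.
Tests passing on this cohort therefore demonstrate the pipeline's
correctness and calibration under its stated assumptions, not clinical
performance on real patients.

## Numerical behaviour worth knowing

**Finite-sample bias of the empirical quantile.** For continuous i.i.d.
data, the probability that a new value exceeds the nearest-rank 95th
centile of *n* training values is `1 − ⌈0.95 n⌉/(n+1)`, not 5%. At
`n = 42` that is 6.98%; at `n = 1500` it is 5.06%. A six-week run-in
therefore alarms on about 7% of stable days *by construction*, and the 5%
nominal rate is reached only as the training window grows. The calibration
tests and the acceptance script measure the converged regime (training
windows of 1,500–5,000 days, 10,000 follow-up days); the run-in-length
effect is a property users should expect in deployment, not a defect.

**Discrete signals are conservative.** The ordinal symptom total ties at
its threshold; strict inequality then makes the stable alert rate *lower*
than nominal (about 2.7% at centile 95 in the stationary test) — the
calibration statement is exact only for continuous signals, and one-sided
for discrete ones.

**Degenerate inputs.** A constant training sample yields its constant as
the threshold in both directions, and strict inequality then guarantees
zero stable alerts — which is why the noiseless recovery test can assert a
false-positive count of exactly zero. Empty event sets propagate as `NA`
proportions; empty usage months are omitted with a warning rather than
interpolated.

**Chance-level linkage.** With a stationary any-signal alert-day
probability `p`, the chance that an event is "preceded" by accident is
`1 − (1 − p)^window`. At the short-run-in alert rates this is large
(≈ 0.5 for three signals and a 3-day window), which is the yardstick the
detection-power test beats, and a caution against reading raw
proportion-preceded values without their chance baseline.

## Usage analytics

Diary/vitals sessions (one per completed day) get lognormal durations whose
median decays exponentially from 110 s toward 45 s with a 25-day time
constant (`usage_params()`): a learning curve calibrated so that from month
3 onward the pooled 95th percentile sits below 100 s while month 1 sits
well above it. Months are consecutive 30-day blocks from each patient's day
0, pooled across patients; `percentile_duration()` shares the nearest-rank
convention (and its oracle test) with the alerting thresholds. Ancillary
sections (care plans, videos with opaque item ids, nurse messages) are
generated at constant daily rates matching per-study access counts of
roughly 10, 4 and 30 per patient.

## Problem sizes in the test suite

The suite runs entirely on generated data: 1,000-sample quantile-oracle
sweeps; a single stable patient with a 1,500-day training window and
10,000 follow-up days for calibration; cohorts of 50 × 180 days
(calibration of means), 20 × 180 (detection power), 100 small cohorts of
3 × 100 (linkage conservation and window monotonicity); everything is
seeded and completes in well under five minutes.

## Limitations

* Alerting is univariate per signal; no joint novelty score is attempted.
* Thresholds are static after the run-in; no adaptive re-estimation.
* Event extraction trusts the medication diary; untreated exacerbations
  are invisible, and a course whose first day falls on a missing diary day
  is observed late.
* The false-positive definition is episode-based and configurable because
  no canonical definition exists at the per-alert level.
* Synthetic-cohort results calibrate and verify the pipeline; they carry
  no evidence about sensitivity or false-alarm burden in a real population.
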