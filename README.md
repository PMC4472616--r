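# copdalert

Personalized alerting for daily COPD telemonitoring data.

People with chronic obstructive pulmonary disease (COPD) who self-monitor at
home produce three daily signals: a symptom-diary score, pulse rate and
oxygen saturation (SpO2). Fixed population-wide alarm limits fit such
patients badly — someone can be stable at an SpO2 that would page a nurse
for someone else. `copdalert` implements the individualized alternative: it
learns each patient's own stable distribution for each signal during an
initial **run-in** period and alerts only on measurements that are extreme
*for that patient*. It then relates those alerts to **exacerbation events**
— days on which the patient starts standby antibiotics and/or oral steroids,
taken from the medication diary — and reports how often events were
anticipated, plus compliance and application-usage analytics. A seeded
synthetic cohort generator makes every stage testable without patient data.

## Method

For patient *i* and signal *s*, let `x_1, …, x_n` be the non-missing values
recorded during the run-in, which ends at the earlier of 42 calendar days
and the day of the 40th completed diary. The package estimates the
empirical CDF

&nbsp;&nbsp;&nbsp;&nbsp;`F̂(x) = (1/n) Σ 1{x_j ≤ x}`

and sets the personalized threshold at the nearest-rank 95th centile in the
direction of clinical deterioration:

* symptom score, pulse: `T = min{ x_j : F̂(x_j) ≥ 0.95 }` — alert when a
  follow-up value is **strictly above** `T`;
* SpO2 (deterioration is downward): `T = max{ x_j : #{x ≥ x_j}/n ≥ 0.95 }`
  — alert when a follow-up value is **strictly below** `T`.

An exacerbation event starts on a medication day preceded by at least 7
medication-free days; an event is *preceded* when any alert falls in the 3
days before its start. Alert days cluster into episodes (gap ≤ 3 days) for
the false-positive count; events with no alert in their window are the
false negatives. Monitoring flags mirror nurse practice: contact after >7
consecutive missing days or 2 consecutive alert days.

## Worked example

```r
library(copdalert)

cohort     <- simulate_cohort(cohort_config(n_patients = 18, n_days = 180, seed = 1))
thresholds <- fit_thresholds(cohort$records)         # 95th-centile run-in thresholds
alerts     <- detect_alerts(cohort$records, thresholds)
events     <- extract_events(cohort$records, merge_gap_days = 7)
evaluate_linkage(cohort$records, alerts, events, thresholds)
```

```
<linkage_result>
  events: 35, preceded by an alert within 3 day(s): 21 (60.0%)
  alert episodes: 181, false positives: 149, false negatives: 14
  compliance: mean 68.6% (range 45.0-97.8%)
```

35 simulated medication-initiation events were found in the diaries; 60%
had at least one alert (any signal) in the 3 preceding days; 14 events had
none. The run-in/follow-up table for the same cohort shows the generator's
calibration — pooled mean (SD) per signal:

```
  signal        run_in_mean run_in_sd followup_mean followup_sd
1 symptom_total        10.1      2.20          10.2        2.64
2 pulse_bpm            82.3     16.0           84.2       16.8
3 spo2_pct             94.0      2.72          93.9        3.10
```

Usage analytics follow the same quantile convention:

```r
log  <- simulate_usage_log(cohort, seed = 2)
late <- log[log$day_index >= 60 & log$section == "diary_vitals", ]
percentile_duration(late, "diary_vitals", 95)   # 85.1 s from month 3 onward
```

`plot_threshold_panel(records, thresholds, "pulse_bpm")` draws the
per-patient trace / histogram / CDF panel with the threshold line, and
`inst/cli/copdalert` wraps the simulate → fit → alert → events → evaluate
chain for shell use.

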