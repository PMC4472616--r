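test_that("an event is preceded only by alerts inside the 3-day window", {
  ev <- make_events("P1", 10)
  in_window <- link_alerts_to_events(make_alerts("P1", 7), ev)
  expect_true(in_window$events$preceded)
  expect_equal(in_window$proportion_preceded, 1)
  expect_equal(in_window$events$linking_alert_days[[1]], 7L)

  out_window <- link_alerts_to_events(make_alerts("P1", 6), ev)
  expect_false(out_window$events$preceded)

  # the event day itself only counts when configured in
  on_day <- link_alerts_to_events(make_alerts("P1", 10), ev)
  expect_false(on_day$events$preceded)
  on_day2 <- link_alerts_to_events(
    make_alerts("P1", 10), ev, linkage_config(include_event_day = TRUE))
  expect_true(on_day2$events$preceded)

  # with no events the proportion is not applicable, not zero
  none <- link_alerts_to_events(make_alerts("P1", 7), make_events("P1", 10)[0, ])
  expect_equal(none$n_events, 0)
  expect_true(is.na(none$proportion_preceded))
})

test_that("alert days cluster into episodes split by the gap", {
  ep <- cluster_alert_episodes(make_alerts("P1", c(5, 6, 9)), gap_days = 3)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$first_day, 5L)
  expect_equal(ep$last_day, 9L)

  far <- cluster_alert_episodes(make_alerts("P1", c(5, 20)), gap_days = 3)
  expect_equal(nrow(far), 2)

  empty <- cluster_alert_episodes(make_alerts("P1", 5)[0, ], gap_days = 3)
  expect_equal(nrow(empty), 0)

  # clustering is per patient
  two <- cluster_alert_episodes(
    make_alerts(c("P1", "P2"), c(5, 6)), gap_days = 3)
  expect_equal(nrow(two), 2)
})

test_that("false positives and negatives follow the episode rule", {
  alerts <- make_alerts("P1", c(5, 6))
  episodes <- cluster_alert_episodes(alerts, 3)

  ev8 <- make_events("P1", 8)
  res <- classify_fp_fn(episodes, ev8, alerts)
  expect_equal(res$n_false_positives, 0)
  expect_equal(res$n_false_negatives, 0)

  res_none <- classify_fp_fn(episodes, ev8[0, ], alerts)
  expect_equal(res_none$n_false_positives, 1)

  silent <- make_alerts("P1", 5)[0, ]
  res_fn <- classify_fp_fn(cluster_alert_episodes(silent, 3), ev8, silent)
  expect_equal(res_fn$n_false_negatives, 1)

  # an event too far after the episode leaves it a false positive
  res_far <- classify_fp_fn(episodes, make_events("P1", 15), alerts)
  expect_equal(res_far$n_false_positives, 1)
  expect_equal(res_far$n_false_negatives, 1)
})

test_that("per-signal alert summaries use the sample SD over patients", {
  alerts <- make_alerts(
    c(rep("A", 2), rep("B", 3), rep("C", 4)),
    c(10, 20, 10, 20, 30, 10, 20, 30, 40),
    "pulse_bpm"
  )
  s <- summarize_alerts(alerts)
  pr <- s[s$signal == "pulse_bpm", ]
  expect_equal(pr$n_alerts, 9)
  expect_equal(pr$n_patients, 3)
  expect_equal(pr$mean_per_patient, 3)
  expect_equal(pr$sd_per_patient, 1)
  # untouched signals report zero totals
  expect_equal(s$n_alerts[s$signal == "spo2_pct"], 0)
  expect_equal(s$mean_per_patient[s$signal == "spo2_pct"], 0)
  # a single alerting patient has no sample SD
  one <- summarize_alerts(make_alerts("A", c(1, 2), "spo2_pct"))
  expect_true(is.na(one$sd_per_patient[one$signal == "spo2_pct"]))
})

test_that("compliance statistics implement the 5-days-per-week rule", {
  full <- make_records(180)
  st <- compliance_stats(full)
  expect_equal(st$per_patient$pct_days_completed, 100)
  expect_true(st$per_patient$five_per_week)

  # exactly 5 completed days in every 7-day block satisfies the rule
  pattern <- rep(c(rep(TRUE, 5), FALSE, FALSE), length.out = 175)
  five <- make_records(175, completed = pattern)
  expect_true(compliance_stats(five)$per_patient$five_per_week)

  # 4 of 7 does not
  pattern4 <- rep(c(rep(TRUE, 4), rep(FALSE, 3)), length.out = 175)
  four <- make_records(175, completed = pattern4)
  expect_false(compliance_stats(four)$per_patient$five_per_week)

  # a 40% compliant patient converges to about 40% of days
  rec <- apply_missingness(make_records(10000), 0.4, seed = 6)
  st2 <- compliance_stats(rec)
  expect_lt(abs(st2$per_patient$pct_days_completed - 40), 2)
})

test_that("the run-in/follow-up table pools patient-days at each split", {
  # noiseless patients at distinct fixed baselines
  recs <- dplyr::bind_rows(
    make_records(100, "A", symptom = 8L, pulse = 70, spo2 = 92),
    make_records(100, "B", symptom = 10L, pulse = 80, spo2 = 94),
    make_records(100, "C", symptom = 12L, pulse = 90, spo2 = 96)
  )
  th <- fit_thresholds(recs, run_in_spec())
  tab <- period_summary(recs, th)
  pr <- tab[tab$signal == "pulse_bpm", ]
  expect_equal(pr$run_in_mean, 80)
  expect_equal(pr$followup_mean, 80)
  # SD reflects only the between-patient spread
  expect_equal(pr$run_in_sd, sd(rep(c(70, 80, 90), each = 40)))

  # empty follow-up leaves the cells not applicable
  short <- make_records(40, "A")
  th_short <- fit_thresholds(short, run_in_spec())
  tab_short <- period_summary(short, th_short)
  expect_true(all(is.na(tab_short$followup_mean)))
})

test_that("preceded plus false negatives always equals the event total", {
  for (seed in 1:25) {
    cfg <- cohort_config(
      n_patients = 4, n_days = 120, seed = seed,
      profile_ranges = list(compliance_prob = c(0.6, 0.98),
                            exacerbation_rate = c(1, 3))
    )
    coh <- simulate_cohort(cfg)
    th <- suppressWarnings(fit_thresholds(coh$records))
    alerts <- detect_alerts(coh$records, th)
    events <- extract_events(coh$records)
    res <- evaluate_linkage(coh$records, alerts, events, th)
    expect_equal(res$linkage$n_events_preceded +
                   res$fp_fn$n_false_negatives,
                 res$linkage$n_events)
  }
})

test_that("wider windows link more events and absolve more episodes", {
  cfg <- cohort_config(n_patients = 8, n_days = 180, seed = 303,
                       profile_ranges = list(exacerbation_rate = c(2, 3)))
  coh <- simulate_cohort(cfg)
  th <- suppressWarnings(fit_thresholds(coh$records))
  alerts <- detect_alerts(coh$records, th)
  events <- extract_events(coh$records)
  episodes <- cluster_alert_episodes(alerts, 3)
  props <- fps <- numeric(0)
  for (w in 1:7) {
    config <- linkage_config(window_days = w)
    props <- c(props, link_alerts_to_events(alerts, events,
                                            config)$proportion_preceded)
    fps <- c(fps, classify_fp_fn(episodes, events, alerts,
                                 config)$n_false_positives)
  }
  expect_true(all(diff(props) >= 0))
  expect_true(all(diff(fps) <= 0))
})

test_that("with no physiological signal, linkage matches the chance rate", {
  cfg <- cohort_config(
    n_patients = 40, n_days = 180, seed = 707,
    profile_ranges = list(compliance_prob = c(0.7, 0.98),
                          exacerbation_rate = c(2, 3)),
    episodes = episode_params(delta_symptom = c(0, 0),
                              delta_pulse = c(0, 0),
                              delta_spo2 = c(0, 0))
  )
  coh <- simulate_cohort(cfg)
  th <- suppressWarnings(fit_thresholds(coh$records))
  alerts <- detect_alerts(coh$records, th)
  events <- extract_events(coh$records)
  res <- link_alerts_to_events(alerts, events)

  # chance of >=1 alert in a 3-day window, from each patient's
  # stationary any-signal alert-day rate
  ends <- unique(th[, c("patient_id", "train_end_day")])
  chance <- vapply(seq_len(nrow(events)), function(i) {
    pid <- events$patient_id[i]
    end <- ends$train_end_day[ends$patient_id == pid]
    if (length(end) == 0) return(NA_real_)
    fu_days <- sum(coh$records$patient_id == pid &
                     coh$records$day_index > end)
    p_day <- length(unique(alerts$day_index[alerts$patient_id == pid])) /
      fu_days
    1 - (1 - p_day)^3
  }, numeric(1))
  expect_lt(abs(res$proportion_preceded - mean(chance, na.rm = TRUE)), 0.15)
})

test_that("noiseless cohorts with long prodromes are fully anticipated", {
  cfg <- noiseless_config(n_patients = 6, n_days = 150, seed = 11,
                          prodrome = 4, rate = 2)
  coh <- simulate_cohort(cfg)
  th <- fit_thresholds(coh$records)
  alerts <- detect_alerts(coh$records, th)
  events <- extract_events(coh$records)
  res <- link_alerts_to_events(alerts, events)
  expect_gt(res$n_events, 0)
  expect_equal(res$proportion_preceded, 1)
  # and the stable days raise no alerts at all outside episodes
  fp <- classify_fp_fn(cluster_alert_episodes(alerts, 3), events, alerts)
  expect_equal(fp$n_false_positives, 0)
})

test_that("the JSON evaluation report round-trips its headline numbers", {
  cfg <- cohort_config(n_patients = 5, n_days = 150, seed = 99)
  coh <- simulate_cohort(cfg)
  th <- suppressWarnings(fit_thresholds(coh$records))
  alerts <- detect_alerts(coh$records, th)
  events <- extract_events(coh$records)
  res <- evaluate_linkage(coh$records, alerts, events, th)
  f <- withr::local_tempfile(fileext = ".json")
  write_linkage_report(res, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$n_events, res$linkage$n_events)
  expect_equal(back$n_false_positives, res$fp_fn$n_false_positives)
  expect_equal(length(back$events), res$linkage$n_events)
})
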