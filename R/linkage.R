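#' Configuration for alert--event linkage
#'
#' @param window_days length of the pre-event window in days (default 3:
#'   an event is "preceded" when an alert falls in the 3 days before
#'   medication initiation).
#' @param include_event_day also count an alert on the medication start day
#'   itself? Default `FALSE` ("prior" reads as strictly before).
#' @param fp_episode_gap_days gap used to cluster alert days into alert
#'   episodes for the false-positive count (default 3).
#' @return an object of class `linkage_config`.
#' @export
linkage_config <- function(window_days = 3, include_event_day = FALSE,
                           fp_episode_gap_days = 3) {
  assert_scalar_number(window_days, "window_days", lower = 1,
                       integerish = TRUE)
  assert_scalar_number(fp_episode_gap_days, "fp_episode_gap_days", lower = 1,
                       integerish = TRUE)
  stopifnot(is.logical(include_event_day), length(include_event_day) == 1L)
  structure(list(window_days = as.integer(window_days),
                 include_event_day = include_event_day,
                 fp_episode_gap_days = as.integer(fp_episode_gap_days)),
            class = "linkage_config")
}

#' Link alerts to exacerbation events over the pre-event window
#'
#' An event starting on day `d` is *preceded* when at least one alert of
#' any signal exists on days `[d - window_days, d - 1]` (extended to `d`
#' itself when `config$include_event_day`). Each event is classified
#' independently.
#'
#' @param alerts alert tibble from [detect_alerts()].
#' @param events event tibble from [extract_events()].
#' @param config a [linkage_config()].
#' @return list: `events` (the events with `preceded` flag and the linking
#'   alert days), `n_events`, `n_events_preceded`, and
#'   `proportion_preceded` (`NA` when there are no events).
#' @export
link_alerts_to_events <- function(alerts, events, config = linkage_config()) {
  stopifnot(inherits(config, "linkage_config"))
  w <- config$window_days
  upper_off <- if (config$include_event_day) 0L else 1L
  linking <- vector("list", nrow(events))
  preceded <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    d <- events$start_day[i]
    window <- (d - w):(d - upper_off)
    hits <- alerts$day_index[alerts$patient_id == events$patient_id[i] &
                               alerts$day_index %in% window]
    hits <- sort(unique(hits))
    linking[[i]] <- hits
    preceded[i] <- length(hits) > 0L
  }
  events$preceded <- preceded
  events$linking_alert_days <- linking
  n <- nrow(events)
  list(events = events,
       n_events = n,
       n_events_preceded = sum(preceded),
       proportion_preceded = if (n == 0L) NA_real_ else mean(preceded))
}

#' Cluster alert days into alert episodes
#'
#' Groups each patient's alert days (any signal) into maximal episodes in
#' which consecutive alert days are at most `gap_days` apart. Alert
#' episodes, rather than single alert days, are the unit used for counting
#' false positives.
#'
#' @param alerts alert tibble.
#' @param gap_days maximum within-episode spacing (default 3).
#' @return tibble: `patient_id`, `first_day`, `last_day`, `n_alert_days`.
#' @export
cluster_alert_episodes <- function(alerts, gap_days = 3) {
  assert_scalar_number(gap_days, "gap_days", lower = 1, integerish = TRUE)
  if (nrow(alerts) == 0L) {
    return(tibble::tibble(patient_id = character(), first_day = integer(),
                          last_day = integer(), n_alert_days = integer()))
  }
  alerts |>
    dplyr::distinct(.data$patient_id, .data$day_index) |>
    dplyr::arrange(.data$patient_id, .data$day_index) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(df, key) {
      days <- df$day_index
      grp <- cumsum(c(TRUE, diff(days) > gap_days))
      tibble::tibble(
        first_day = as.integer(tapply(days, grp, min)),
        last_day = as.integer(tapply(days, grp, max)),
        n_alert_days = as.integer(tapply(days, grp, length))
      )
    }) |>
    dplyr::ungroup()
}

#' False-positive and false-negative counts
#'
#' A false negative is an event with no alert in its pre-event window (per
#' [link_alerts_to_events()]). A false positive is an alert episode that
#' corresponds to no event: no event starts inside the episode nor within
#' `window_days` after its last alert day.
#'
#' @param episodes alert episodes from [cluster_alert_episodes()].
#' @param events event tibble.
#' @param alerts alert tibble (used for the false-negative side).
#' @param config a [linkage_config()].
#' @return list: `n_false_positives`, `n_false_negatives`,
#'   `false_positive_episodes`, `false_negative_events`.
#' @export
classify_fp_fn <- function(episodes, events, alerts,
                           config = linkage_config()) {
  stopifnot(inherits(config, "linkage_config"))
  w <- config$window_days
  fp <- logical(nrow(episodes))
  for (i in seq_len(nrow(episodes))) {
    ev_days <- events$start_day[events$patient_id == episodes$patient_id[i]]
    fp[i] <- !any(ev_days >= episodes$first_day[i] &
                    ev_days <= episodes$last_day[i] + w)
  }
  linked <- link_alerts_to_events(alerts, events, config)
  fn_events <- linked$events[!linked$events$preceded, , drop = FALSE]
  list(n_false_positives = sum(fp),
       n_false_negatives = nrow(fn_events),
       false_positive_episodes = episodes[fp, , drop = FALSE],
       false_negative_events = fn_events)
}

#' Per-signal alert summaries
#'
#' For each signal: the total number of alerts, the number of patients with
#' at least one alert, and the mean and SD (sample SD, denominator n-1,
#' over the patients with at least one alert) of per-patient alert counts.
#' With a single alerting patient the SD is reported as `NA`.
#'
#' @param alerts alert tibble.
#' @param signals signals to summarize.
#' @return tibble with one row per signal.
#' @export
summarize_alerts <- function(alerts, signals = SIGNALS) {
  out <- lapply(signals, function(sig) {
    a <- alerts[alerts$signal == sig, ]
    counts <- as.numeric(table(a$patient_id))
    tibble::tibble(
      signal = sig,
      n_alerts = nrow(a),
      n_patients = length(counts),
      mean_per_patient = if (length(counts)) mean(counts) else 0,
      sd_per_patient = if (length(counts) >= 2L) sd(counts) else NA_real_
    )
  })
  dplyr::bind_rows(out)
}

#' Compliance statistics
#'
#' Per patient, the percentage of study days with a completed record;
#' cohort mean and range; and the fraction of patients who completed at
#' least 5 days out of 7 in *every* week of the study. Weeks are
#' consecutive 7-day blocks from each patient's day 0, with a final partial
#' week prorated (at least 5/7 of its days).
#'
#' @param records cohort daily records.
#' @return list: `per_patient` tibble (`patient_id`, `pct_days_completed`,
#'   `five_per_week`), `mean_pct`, `range_pct`, and
#'   `prop_five_per_week`.
#' @export
compliance_stats <- function(records) {
  per_patient <- records |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      pct_days_completed = 100 * mean(.data$completed),
      five_per_week = {
        block <- .data$day_index %/% 7L
        frac <- tapply(.data$completed, block, mean)
        all(frac >= 5 / 7 - 1e-9)
      },
      .groups = "drop"
    )
  list(per_patient = per_patient,
       mean_pct = mean(per_patient$pct_days_completed),
       range_pct = range(per_patient$pct_days_completed),
       prop_five_per_week = mean(per_patient$five_per_week))
}

#' Run-in versus follow-up summary of the monitored signals
#'
#' Pooled mean and SD of each signal over all patient-days, split at each
#' patient's run-in end. Days belonging to patients without a fitted
#' run-in are omitted; empty cells are `NA`.
#'
#' @param records cohort daily records.
#' @param thresholds threshold tibble from [fit_thresholds()] (defines each
#'   patient's `train_end_day`), or a tibble with `patient_id` and
#'   `train_end_day`.
#' @return tibble with one row per signal: `run_in_mean`, `run_in_sd`,
#'   `followup_mean`, `followup_sd`.
#' @export
period_summary <- function(records, thresholds) {
  ends <- dplyr::distinct(thresholds[, c("patient_id", "train_end_day")])
  joined <- dplyr::inner_join(records, ends, by = "patient_id")
  pooled <- function(x) {
    x <- x[!is.na(x)]
    c(mean = if (length(x)) mean(x) else NA_real_,
      sd = if (length(x) >= 2L) sd(x) else NA_real_)
  }
  rows <- lapply(SIGNALS, function(sig) {
    run_in <- joined[[sig]][joined$day_index <= joined$train_end_day]
    follow <- joined[[sig]][joined$day_index > joined$train_end_day]
    ri <- pooled(run_in)
    fu <- pooled(follow)
    tibble::tibble(signal = sig,
                   run_in_mean = unname(ri["mean"]),
                   run_in_sd = unname(ri["sd"]),
                   followup_mean = unname(fu["mean"]),
                   followup_sd = unname(fu["sd"]))
  })
  dplyr::bind_rows(rows)
}

#' Full alert--event evaluation report
#'
#' Convenience wrapper producing every summary of the evaluation in one
#' structure: linkage of events to preceding alerts, alert-episode
#' false positives and event false negatives, per-signal alert summaries,
#' compliance statistics and the run-in/follow-up table.
#'
#' @param records cohort daily records.
#' @param alerts alert tibble.
#' @param events event tibble.
#' @param thresholds threshold tibble.
#' @param config a [linkage_config()].
#' @return list of class `linkage_result`.
#' @export
evaluate_linkage <- function(records, alerts, events, thresholds,
                             config = linkage_config()) {
  linked <- link_alerts_to_events(alerts, events, config)
  episodes <- cluster_alert_episodes(alerts, config$fp_episode_gap_days)
  fpfn <- classify_fp_fn(episodes, events, alerts, config)
  structure(
    list(config = config,
         linkage = linked,
         alert_episodes = episodes,
         fp_fn = fpfn,
         alert_summary = summarize_alerts(alerts),
         compliance = compliance_stats(records),
         period_summary = period_summary(records, thresholds)),
    class = "linkage_result"
  )
}

#' @export
print.linkage_result <- function(x, ...) {
  l <- x$linkage
  cat("<linkage_result>\n")
  cat(sprintf("  events: %d, preceded by an alert within %d day(s): %d (%s)\n",
              l$n_events, x$config$window_days, l$n_events_preceded,
              if (is.na(l$proportion_preceded)) "n/a"
              else sprintf("%.1f%%", 100 * l$proportion_preceded)))
  cat(sprintf("  alert episodes: %d, false positives: %d, false negatives: %d\n",
              nrow(x$alert_episodes), x$fp_fn$n_false_positives,
              x$fp_fn$n_false_negatives))
  cat(sprintf("  compliance: mean %.1f%% (range %.1f-%.1f%%)\n",
              x$compliance$mean_pct, x$compliance$range_pct[1],
              x$compliance$range_pct[2]))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param result a `linkage_result` from [evaluate_linkage()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_linkage_report <- function(result, path) {
  stopifnot(inherits(result, "linkage_result"))
  events <- result$linkage$events
  events$linking_alert_days <- vapply(
    events$linking_alert_days,
    function(d) paste(d, collapse = ";"), character(1))
  out <- list(
    window_days = result$config$window_days,
    n_events = result$linkage$n_events,
    n_events_preceded = result$linkage$n_events_preceded,
    proportion_preceded = result$linkage$proportion_preceded,
    n_false_positives = result$fp_fn$n_false_positives,
    n_false_negatives = result$fp_fn$n_false_negatives,
    alert_summary = result$alert_summary,
    compliance = list(
      mean_pct = result$compliance$mean_pct,
      range_pct = result$compliance$range_pct,
      prop_five_per_week = result$compliance$prop_five_per_week
    ),
    period_summary = result$period_summary,
    events = events
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
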