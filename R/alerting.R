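#' Run-in (training) period specification
#'
#' The personalized thresholds are estimated over an initial run-in period,
#' which ends at the *earlier* of `max_calendar_days` calendar days and the
#' day on which the patient's `max_diaries`-th completed record occurs.
#' Defaults follow the 6-week / 40-diaries convention.
#'
#' @param max_calendar_days calendar bound on the run-in (default 42).
#' @param max_diaries bound on completed diaries in the run-in (default 40).
#' @param min_train minimum completed records a patient needs before
#'   thresholds are fitted at all (default 10).
#' @return an object of class `run_in_spec`.
#' @export
run_in_spec <- function(max_calendar_days = 42, max_diaries = 40,
                        min_train = 10) {
  assert_scalar_number(max_calendar_days, "max_calendar_days", lower = 1,
                       integerish = TRUE)
  assert_scalar_number(max_diaries, "max_diaries", lower = 1,
                       integerish = TRUE)
  assert_scalar_number(min_train, "min_train", lower = 1, integerish = TRUE)
  structure(list(max_calendar_days = as.integer(max_calendar_days),
                 max_diaries = as.integer(max_diaries),
                 min_train = as.integer(min_train)),
            class = "run_in_spec")
}

#' Select one patient's run-in window
#'
#' @param records daily records of a single patient.
#' @param spec a [run_in_spec()].
#' @return list with `train_start_day` (always 0), `train_end_day` (last
#'   day index inside the run-in) and `n_completed` (completed diaries in
#'   the window).
#' @export
select_run_in <- function(records, spec = run_in_spec()) {
  stopifnot(inherits(spec, "run_in_spec"))
  if (nrow(records) == 0L) {
    abort("`records` must be non-empty.")
  }
  if (dplyr::n_distinct(records$patient_id) != 1L) {
    abort("`select_run_in()` expects the records of a single patient.")
  }
  records <- dplyr::arrange(records, .data$day_index)
  n_completed_total <- sum(records$completed)
  if (n_completed_total < spec$min_train) {
    abort(sprintf(
      "patient %s has only %d completed records; at least %d are required to fit thresholds.",
      records$patient_id[1], n_completed_total, spec$min_train))
  }
  completed_days <- records$day_index[records$completed]
  calendar_end <- spec$max_calendar_days - 1L
  diary_end <- if (length(completed_days) >= spec$max_diaries) {
    completed_days[spec$max_diaries]
  } else {
    Inf
  }
  end_day <- as.integer(min(calendar_end, diary_end))
  list(train_start_day = 0L,
       train_end_day = end_day,
       n_completed = sum(completed_days <= end_day))
}

#' Empirical cumulative distribution function of training values
#'
#' Right-continuous step function: `F(x)` is the fraction of training
#' values less than or equal to `x`.
#'
#' @param values numeric vector with at least one non-missing value.
#' @return a function of class `ecdf`.
#' @export
empirical_cdf <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    abort("`values` must contain at least one non-missing number.")
  }
  stats::ecdf(values)
}

#' Personalized alert threshold from training values
#'
#' For an upper-tail signal (symptom score, pulse rate) the threshold is
#' the nearest-rank quantile of the training values at `centile`: the
#' smallest training value whose empirical CDF reaches `centile/100`. For
#' a lower-tail signal (oxygen saturation) the rule is mirrored into the
#' lower tail: the largest training value `v` such that at least
#' `centile/100` of the training values are `>= v`. A follow-up
#' measurement alerts when it is strictly beyond the threshold in the
#' alerting direction.
#'
#' Optionally (`method = "kernel"`) the CDF is estimated with a Gaussian
#' kernel (bandwidth `stats::bw.nrd0`) and the threshold is the smooth
#' CDF's quantile; this gives a threshold between training values instead
#' of exactly at one.
#'
#' @param values training values (`NA`s dropped).
#' @param centile percentage in (0, 100); default 95.
#' @param direction `"upper"` or `"lower"`.
#' @param min_train minimum non-missing training values required.
#' @param method `"nearest_rank"` (default) or `"kernel"`.
#' @return the threshold, in the units of `values`.
#' @examples
#' compute_threshold(1:100, 95, "upper") # 95
#' compute_threshold(1:100, 95, "lower") # 6
#' @export
compute_threshold <- function(values, centile = 95,
                              direction = c("upper", "lower"),
                              min_train = 10,
                              method = c("nearest_rank", "kernel")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  assert_scalar_number(centile, "centile")
  if (centile <= 0 || centile >= 100) {
    abort("`centile` must be strictly between 0 and 100.")
  }
  values <- values[!is.na(values)]
  if (length(values) < min_train) {
    abort(sprintf("need at least %d non-missing training values, got %d.",
                  min_train, length(values)))
  }
  p <- centile / 100
  if (method == "nearest_rank") {
    nearest_rank_quantile(values, p, direction)
  } else {
    kernel_quantile(values, p, direction)
  }
}

# Quantile of the Gaussian-kernel-smoothed CDF,
# F(x) = mean(pnorm((x - x_i) / h)). The lower direction mirrors the
# target probability into the lower tail.
kernel_quantile <- function(values, p, direction) {
  h <- stats::bw.nrd0(values)
  if (h <= 0) {
    return(nearest_rank_quantile(values, p, direction))
  }
  target <- if (direction == "upper") p else 1 - p
  f <- function(x) mean(pnorm((x - values) / h)) - target
  lo <- min(values) - 10 * h
  hi <- max(values) + 10 * h
  uniroot(f, c(lo, hi), tol = 1e-9)$root
}

#' Fit per-patient, per-signal alert thresholds over the run-in
#'
#' Selects each patient's run-in window with [select_run_in()] and computes
#' a directional threshold per signal from the completed records inside it:
#' upper-tail for `symptom_total` and `pulse_bpm`, lower-tail for
#' `spo2_pct`. Patients whose run-in holds fewer than `min_train`
#' non-missing values for a signal are excluded from alerting on that
#' signal, with a warning.
#'
#' @param records cohort daily records (all patients).
#' @param spec a [run_in_spec()].
#' @param centile alert centile, interpreted in each signal's alerting
#'   direction (default 95).
#' @param signals which signals to fit (default all three).
#' @param method quantile estimator, see [compute_threshold()].
#' @return tibble of threshold models: `patient_id`, `signal`, `direction`,
#'   `centile`, `threshold`, `n_train`, `train_start_day`, `train_end_day`.
#' @export
fit_thresholds <- function(records, spec = run_in_spec(), centile = 95,
                           signals = SIGNALS,
                           method = c("nearest_rank", "kernel")) {
  method <- match.arg(method)
  signals <- match.arg(signals, SIGNALS, several.ok = TRUE)
  rows <- list()
  for (pid in unique(records$patient_id)) {
    p_rec <- records[records$patient_id == pid, ]
    window <- tryCatch(select_run_in(p_rec, spec), error = function(e) e)
    if (inherits(window, "error")) {
      warn(sprintf("excluding patient %s from alerting: %s",
                   pid, conditionMessage(window)))
      next
    }
    train <- p_rec[p_rec$day_index <= window$train_end_day, ]
    for (sig in signals) {
      values <- train[[sig]][!is.na(train[[sig]])]
      if (length(values) < spec$min_train) {
        warn(sprintf(
          "excluding patient %s signal %s: %d non-missing training values (< %d).",
          pid, sig, length(values), spec$min_train))
        next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = pid,
        signal = sig,
        direction = unname(SIGNAL_DIRECTIONS[sig]),
        centile = centile,
        threshold = compute_threshold(values, centile,
                                      SIGNAL_DIRECTIONS[sig],
                                      min_train = spec$min_train,
                                      method = method),
        n_train = length(values),
        train_start_day = window$train_start_day,
        train_end_day = window$train_end_day
      )
    }
  }
  if (length(rows) == 0L) {
    abort("no patient had enough training data to fit any threshold.")
  }
  dplyr::bind_rows(rows)
}

#' Detect alerts on follow-up days
#'
#' Tests every non-missing signal value on days after the patient's run-in
#' against the personalized threshold and emits an alert when the value is
#' strictly beyond it in the alerting direction (`>` threshold for symptom
#' score and pulse, `<` threshold for oxygen saturation). A value exactly
#' at the threshold never alerts; run-in days and missing days never alert.
#'
#' @param records cohort daily records.
#' @param thresholds threshold tibble from [fit_thresholds()].
#' @return tibble of alerts: `patient_id`, `day_index`, `signal`, `value`,
#'   `threshold`, `direction`.
#' @export
detect_alerts <- function(records, thresholds) {
  long <- records |>
    dplyr::select(dplyr::all_of(c("patient_id", "day_index", SIGNALS))) |>
    tidyr::pivot_longer(dplyr::all_of(SIGNALS), names_to = "signal",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  joined <- dplyr::inner_join(long, thresholds,
                              by = c("patient_id", "signal"))
  alerts <- joined |>
    dplyr::filter(.data$day_index > .data$train_end_day,
                  (.data$direction == "upper" & .data$value > .data$threshold) |
                    (.data$direction == "lower" & .data$value < .data$threshold)) |>
    dplyr::arrange(.data$patient_id, .data$day_index, .data$signal)
  alerts[, c("patient_id", "day_index", "signal", "value", "threshold",
             "direction")]
}

#' Flag runs of consecutive alert days
#'
#' The monitoring rule contacts a patient who is in the alert zone for `k`
#' consecutive days (default 2). By default a day counts as an alert day
#' when any signal alerts on it; with `by_signal = TRUE` the run must occur
#' within a single signal.
#'
#' @param alerts alert tibble from [detect_alerts()].
#' @param k run length required (default 2).
#' @param by_signal require the consecutive days within one signal?
#' @return tibble of contact flags: `patient_id`, `day_index` (the day the
#'   run completes) and, if `by_signal`, the `signal`.
#' @export
flag_consecutive_alerts <- function(alerts, k = 2, by_signal = FALSE) {
  assert_scalar_number(k, "k", lower = 1, integerish = TRUE)
  flag_one <- function(days) {
    days <- sort(unique(days))
    if (length(days) == 0L) return(integer())
    # day d flags iff d, d-1, ..., d-k+1 are all alert days
    days[vapply(days, function(d) all((d - seq_len(k) + 1L) %in% days),
                logical(1))]
  }
  if (by_signal) {
    out <- alerts |>
      dplyr::group_by(.data$patient_id, .data$signal) |>
      dplyr::reframe(day_index = flag_one(.data$day_index))
  } else {
    out <- alerts |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::reframe(day_index = flag_one(.data$day_index))
  }
  dplyr::arrange(out, .data$patient_id, .data$day_index)
}

#' Flag long gaps of missing data
#'
#' The monitoring rule contacts a patient after a period of missing data
#' longer than `gap_days` (default 7): one flag per maximal run of
#' consecutive non-completed days of length strictly greater than
#' `gap_days`.
#'
#' @param records cohort daily records.
#' @param gap_days threshold run length (default 7; a 7-day gap does not
#'   flag, an 8-day gap does).
#' @return tibble: `patient_id`, `gap_start_day`, `gap_length`.
#' @export
flag_missing_gaps <- function(records, gap_days = 7) {
  assert_scalar_number(gap_days, "gap_days", lower = 1, integerish = TRUE)
  records |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$day_index)
      r <- rle(!df$completed)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths > gap_days
      tibble::tibble(
        gap_start_day = df$day_index[starts[keep]],
        gap_length = r$lengths[keep]
      )
    }) |>
    dplyr::ungroup()
}
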