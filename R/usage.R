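#' Parameters of the simulated application-usage log
#'
#' Session durations are lognormal; the median duration of a
#' `diary_vitals` session (completing the diary plus the oximetry reading)
#' decays exponentially with days on study from `initial_median_s` toward
#' `asymptote_median_s` with time constant `tau_days` -- a learning curve.
#' Ancillary sections are generated at constant daily rates calibrated to
#' the per-study access counts reported for self-management plans (about
#' 10 per patient), videos (about 4) and nurse messages (about 30) over
#' 180 days.
#'
#' @param initial_median_s median diary/vitals duration on day 0 (seconds).
#' @param asymptote_median_s long-run median duration (seconds).
#' @param tau_days exponential time constant of the learning curve (days);
#'   0 disables learning (constant median).
#' @param sdlog lognormal shape of session durations.
#' @param section_rates per-day Bernoulli rates of ancillary sessions.
#' @param section_medians_s median durations of ancillary sessions.
#' @param n_videos number of distinct video clips (item ids).
#' @return named list of parameters.
#' @export
usage_params <- function(initial_median_s = 110,
                         asymptote_median_s = 45,
                         tau_days = 25,
                         sdlog = 0.35,
                         section_rates = c(care_plan = 0.055,
                                           video = 0.022,
                                           message = 0.165),
                         section_medians_s = c(care_plan = 60,
                                               video = 90,
                                               message = 30),
                         n_videos = 14) {
  assert_scalar_number(initial_median_s, "initial_median_s", lower = 1)
  assert_scalar_number(asymptote_median_s, "asymptote_median_s", lower = 1)
  assert_scalar_number(tau_days, "tau_days", lower = 0)
  assert_scalar_number(sdlog, "sdlog", lower = 0)
  list(initial_median_s = initial_median_s,
       asymptote_median_s = asymptote_median_s,
       tau_days = tau_days, sdlog = sdlog,
       section_rates = section_rates,
       section_medians_s = section_medians_s,
       n_videos = as.integer(n_videos))
}

# Median diary/vitals duration after `day` days on study.
learning_median <- function(day, params) {
  if (params$tau_days <= 0) {
    return(rep(params$initial_median_s, length(day)))
  }
  params$asymptote_median_s +
    (params$initial_median_s - params$asymptote_median_s) *
    exp(-day / params$tau_days)
}

#' Simulate an application-usage log for a cohort
#'
#' One `diary_vitals` session per completed study day, with duration drawn
#' from the learning-curve lognormal of [usage_params()]; ancillary
#' sessions (care plan, videos, nurse messages) drawn at their daily rates
#' on any study day. Videos carry an opaque `item_id`.
#'
#' @param cohort a `copd_cohort`.
#' @param params a [usage_params()].
#' @param seed optional integer.
#' @return tibble of sessions: `patient_id`, `day_index`, `date`,
#'   `section`, `item_id`, `duration_s`.
#' @export
simulate_usage_log <- function(cohort, params = usage_params(), seed = NULL) {
  stopifnot(inherits(cohort, "copd_cohort"))
  records <- cohort$records
  with_seed(seed, {
    diary <- records[records$completed, ]
    diary_sessions <- tibble::tibble(
      patient_id = diary$patient_id,
      day_index = diary$day_index,
      date = diary$date,
      section = "diary_vitals",
      item_id = NA_character_,
      duration_s = rlnorm(nrow(diary),
                          meanlog = log(learning_median(diary$day_index,
                                                        params)),
                          sdlog = params$sdlog)
    )
    extra <- list()
    for (sec in names(params$section_rates)) {
      hit <- runif(nrow(records)) < params$section_rates[[sec]]
      n <- sum(hit)
      if (n == 0L) next
      extra[[sec]] <- tibble::tibble(
        patient_id = records$patient_id[hit],
        day_index = records$day_index[hit],
        date = records$date[hit],
        section = sec,
        item_id = if (sec == "video") {
          sprintf("video_%02d", sample.int(params$n_videos, n, replace = TRUE))
        } else {
          NA_character_
        },
        duration_s = rlnorm(n, meanlog = log(params$section_medians_s[[sec]]),
                            sdlog = params$sdlog)
      )
    }
    out <- dplyr::bind_rows(c(list(diary_sessions), extra))
    dplyr::arrange(out, .data$patient_id, .data$day_index, .data$section)
  })
}

#' Monthly empirical CDFs of session durations
#'
#' Pools the durations of one section across all patients within each
#' 30-day study month (months counted from each patient's day 0) and
#' returns the empirical CDF per month. Empty months are omitted with a
#' warning.
#'
#' @param sessions usage-log tibble.
#' @param section section to analyse (default `"diary_vitals"`).
#' @param month_days days per study month (default 30).
#' @return named list of `ecdf` functions, one per month (`"month_1"` is
#'   days 0--29).
#' @export
monthly_duration_cdf <- function(sessions, section = "diary_vitals",
                                 month_days = 30) {
  s <- sessions[sessions$section == section, ]
  if (nrow(s) == 0L) {
    abort(sprintf("no sessions for section '%s'.", section))
  }
  month <- s$day_index %/% as.integer(month_days)
  months <- seq(0L, max(month))
  out <- list()
  for (m in months) {
    durations <- s$duration_s[month == m]
    if (length(durations) == 0L) {
      warn(sprintf("month %d has no '%s' sessions; omitted.", m + 1L, section))
      next
    }
    out[[sprintf("month_%d", m + 1L)]] <- empirical_cdf(durations)
  }
  out
}

#' Nearest-rank percentile of session durations
#'
#' Same quantile convention as the alert thresholds: the smallest observed
#' duration whose empirical CDF reaches `p/100`.
#'
#' @param sessions usage-log tibble.
#' @param section section to analyse.
#' @param p percentile in (0, 100].
#' @return duration in seconds.
#' @examples
#' \dontrun{percentile_duration(log, "diary_vitals", 95)}
#' @export
percentile_duration <- function(sessions, section = "diary_vitals", p = 95) {
  assert_scalar_number(p, "p")
  if (p <= 0 || p > 100) {
    abort("`p` must be in (0, 100].")
  }
  durations <- sessions$duration_s[sessions$section == section]
  durations <- durations[!is.na(durations)]
  if (length(durations) == 0L) {
    abort(sprintf("no sessions for section '%s'.", section))
  }
  nearest_rank_quantile(durations, p / 100, "upper")
}
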