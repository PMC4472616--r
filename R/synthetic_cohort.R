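#' Default sampling ranges for patient profiles
#'
#' Each element is a `c(min, max)` pair from which [sample_profiles()] draws
#' uniformly, one value per patient. Baseline means are centred on the
#' run-in summary statistics of the monitored cohort the generator emulates
#' (symptom score 9.6, pulse 83.4 beats/min, SpO2 93.8\%); the spread across
#' patients plus the daily noise SDs together reproduce pooled SDs of the
#' same order as observed (approximately 2.4 score units, 17 beats/min,
#' 3\% saturation). Compliance spans the observed 40--98\% range of days
#' completed, and the exacerbation rate averages about two self-treated
#' episodes per patient per 180 days.
#'
#' @return named list of `c(min, max)` ranges.
#' @export
default_profile_ranges <- function() {
  list(
    baseline_symptom  = c(7.6, 11.6),
    baseline_pulse    = c(68.4, 98.4),
    baseline_spo2     = c(91.3, 96.3),
    noise_sd_symptom  = c(1.5, 2.5),
    noise_sd_pulse    = c(10, 18),
    noise_sd_spo2     = c(1.8, 3.2),
    autocorr          = c(0.2, 0.5),
    compliance_prob   = c(0.40, 0.98),
    exacerbation_rate = c(0.5, 3.6)
  )
}

#' Default exacerbation episode parameters
#'
#' Controls how simulated exacerbation episodes look: a prodromal drift of
#' a few days before the patient starts standby medication, a treatment
#' course of about a week, and additive physiological shifts (symptom score
#' and pulse rise, oxygen saturation falls). `min_gap_days` is the minimum
#' separation enforced between consecutive episodes of one patient, and
#' `runin_guard_days` keeps episode onsets out of the initial window that
#' downstream threshold fitting uses as a stable baseline.
#'
#' @param prodrome_days integer `c(min, max)` days of pre-medication drift.
#' @param course_days integer `c(min, max)` days of the medication course.
#' @param delta_symptom additive symptom-score shift range (score units).
#' @param delta_pulse additive pulse shift range (beats/min).
#' @param delta_spo2 subtractive oxygen-saturation shift range (percentage
#'   points).
#' @param med_type_probs named probabilities for the drug combination a
#'   patient initiates.
#' @param min_gap_days minimum days between one episode's last course day
#'   and the next episode's onset.
#' @param runin_guard_days earliest allowed onset day (set 0 to allow
#'   episodes during the run-in).
#' @return named list of episode parameters.
#' @export
episode_params <- function(prodrome_days = c(2, 5),
                           course_days = c(5, 10),
                           delta_symptom = c(3, 6),
                           delta_pulse = c(8, 18),
                           delta_spo2 = c(2, 5),
                           med_type_probs = c(antibiotics = 0.4,
                                              steroids = 0.2,
                                              both = 0.4),
                           min_gap_days = 14,
                           runin_guard_days = 42) {
  assert_range(prodrome_days, "prodrome_days", lower = 0)
  assert_range(course_days, "course_days", lower = 1)
  assert_range(delta_symptom, "delta_symptom", lower = 0)
  assert_range(delta_pulse, "delta_pulse", lower = 0)
  assert_range(delta_spo2, "delta_spo2", lower = 0)
  if (!setequal(names(med_type_probs), c("antibiotics", "steroids", "both")) ||
      any(med_type_probs < 0) || sum(med_type_probs) <= 0) {
    abort("`med_type_probs` must be non-negative probabilities named antibiotics, steroids, both.")
  }
  assert_scalar_number(min_gap_days, "min_gap_days", lower = 1, integerish = TRUE)
  assert_scalar_number(runin_guard_days, "runin_guard_days", lower = 0,
                       integerish = TRUE)
  list(prodrome_days = prodrome_days, course_days = course_days,
       delta_symptom = delta_symptom, delta_pulse = delta_pulse,
       delta_spo2 = delta_spo2,
       med_type_probs = med_type_probs / sum(med_type_probs),
       min_gap_days = min_gap_days, runin_guard_days = runin_guard_days)
}

#' Configuration for a synthetic telemonitoring cohort
#'
#' @param n_patients number of patients (default 18, the size of the cohort
#'   the generator emulates).
#' @param n_days study length in days (default 180, a six-month study).
#' @param seed integer fixing all randomness of the cohort.
#' @param profile_ranges see [default_profile_ranges()].
#' @param episodes see [episode_params()].
#' @param start_date calendar date of `day_index` 0.
#' @param symptom_scale_max maximum of the total symptom score; the diary has
#'   five items (well-being, cough, sputum quantity, sputum colour,
#'   breathlessness) each scored 0 to `symptom_scale_max / 5`.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 18,
                          n_days = 180,
                          seed = 1L,
                          profile_ranges = default_profile_ranges(),
                          episodes = episode_params(),
                          start_date = as.Date("2014-01-01"),
                          symptom_scale_max = 20) {
  assert_scalar_number(n_patients, "n_patients", lower = 1, integerish = TRUE)
  assert_scalar_number(n_days, "n_days", lower = 1, integerish = TRUE)
  assert_scalar_number(seed, "seed", integerish = TRUE)
  assert_scalar_number(symptom_scale_max, "symptom_scale_max", lower = 5,
                       integerish = TRUE)
  if (symptom_scale_max %% 5 != 0) {
    abort("`symptom_scale_max` must be a multiple of 5 (five diary items).")
  }
  defaults <- default_profile_ranges()
  missing_fields <- setdiff(names(defaults), names(profile_ranges))
  profile_ranges <- c(profile_ranges, defaults[missing_fields])
  assert_range(profile_ranges$baseline_symptom, "baseline_symptom",
               lower = 0, upper = symptom_scale_max)
  assert_range(profile_ranges$baseline_pulse, "baseline_pulse", lower = 1)
  assert_range(profile_ranges$baseline_spo2, "baseline_spo2",
               lower = 1, upper = 100)
  assert_range(profile_ranges$noise_sd_symptom, "noise_sd_symptom", lower = 0)
  assert_range(profile_ranges$noise_sd_pulse, "noise_sd_pulse", lower = 0)
  assert_range(profile_ranges$noise_sd_spo2, "noise_sd_spo2", lower = 0)
  assert_range(profile_ranges$autocorr, "autocorr", lower = 0, upper = 1)
  if (profile_ranges$autocorr[2] >= 1) {
    abort("`autocorr` must be strictly below 1.")
  }
  assert_range(profile_ranges$compliance_prob, "compliance_prob",
               lower = 0, upper = 1)
  assert_range(profile_ranges$exacerbation_rate, "exacerbation_rate",
               lower = 0)
  structure(
    list(n_patients = as.integer(n_patients),
         n_days = as.integer(n_days),
         seed = as.integer(seed),
         profile_ranges = profile_ranges[names(defaults)],
         episodes = episodes,
         start_date = as.Date(start_date),
         symptom_scale_max = as.integer(symptom_scale_max)),
    class = "cohort_config"
  )
}

runif_range <- function(n, range) runif(n, range[1], range[2])

# uniform integer draw on [lo, hi], safe when lo == hi
sample_int_range <- function(lo, hi) {
  if (lo >= hi) as.integer(lo) else
    as.integer(lo + sample.int(hi - lo + 1L, 1L) - 1L)
}

#' Sample per-patient profiles for a synthetic cohort
#'
#' Draws `config$n_patients` patient profiles, each field uniform within its
#' configured range, deterministically under `config$seed`. With a
#' zero-width range every patient receives the midpoint exactly.
#'
#' @param config a [cohort_config()].
#' @return tibble with one row per patient: baselines, noise SDs, lag-1
#'   autocorrelation, per-day compliance probability and expected
#'   exacerbation episodes per 180 days.
#' @export
sample_profiles <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  r <- config$profile_ranges
  with_seed(config$seed, {
    tibble::tibble(
      patient_id        = sprintf("P%03d", seq_len(n)),
      baseline_symptom  = runif_range(n, r$baseline_symptom),
      baseline_pulse    = runif_range(n, r$baseline_pulse),
      baseline_spo2     = runif_range(n, r$baseline_spo2),
      noise_sd_symptom  = runif_range(n, r$noise_sd_symptom),
      noise_sd_pulse    = runif_range(n, r$noise_sd_pulse),
      noise_sd_spo2     = runif_range(n, r$noise_sd_spo2),
      autocorr          = runif_range(n, r$autocorr),
      compliance_prob   = runif_range(n, r$compliance_prob),
      exacerbation_rate = runif_range(n, r$exacerbation_rate)
    )
  })
}

# Stationary AR(1) noise with marginal standard deviation `sd`.
ar1_noise <- function(n, sd, autocorr) {
  if (sd == 0 || n == 0L) {
    return(numeric(n))
  }
  z <- rnorm(n)
  e <- numeric(n)
  e[1] <- sd * z[1]
  if (n > 1L) {
    innov_sd <- sd * sqrt(1 - autocorr^2)
    for (t in 2:n) {
      e[t] <- autocorr * e[t - 1] + innov_sd * z[t]
    }
  }
  e
}

sample_episodes <- function(profile, config) {
  ep <- config$episodes
  n_days <- config$n_days
  lambda <- profile$exacerbation_rate * n_days / 180
  n_target <- rpois(1L, lambda)
  out <- list()
  taken <- logical(n_days) # occupied day_index + 1
  for (i in seq_len(n_target)) {
    placed <- FALSE
    for (attempt in seq_len(200L)) {
      prodrome <- sample_int_range(ep$prodrome_days[1], ep$prodrome_days[2])
      course <- sample_int_range(ep$course_days[1], ep$course_days[2])
      span <- prodrome + course
      lo <- ep$runin_guard_days
      hi <- n_days - span
      if (hi < lo) break
      onset <- sample_int_range(lo, hi)
      # occupy the episode plus the enforced gap on both sides
      block <- max(0L, onset - ep$min_gap_days):
        min(n_days - 1L, onset + span - 1L + ep$min_gap_days)
      if (any(taken[block + 1L])) next
      taken[onset:(onset + span - 1L) + 1L] <- TRUE
      out[[length(out) + 1L]] <- tibble::tibble(
        patient_id    = profile$patient_id,
        onset_day     = as.integer(onset),
        prodrome_days = as.integer(prodrome),
        med_start_day = as.integer(onset + prodrome),
        course_days   = as.integer(course),
        delta_symptom = runif_range(1L, ep$delta_symptom),
        delta_pulse   = runif_range(1L, ep$delta_pulse),
        delta_spo2    = runif_range(1L, ep$delta_spo2),
        med_type      = sample(names(ep$med_type_probs), 1L,
                               prob = ep$med_type_probs)
      )
      placed <- TRUE
      break
    }
    if (!placed) next
  }
  if (length(out) == 0L) empty_episodes() else
    dplyr::arrange(dplyr::bind_rows(out), .data$onset_day)
}

empty_episodes <- function() {
  tibble::tibble(
    patient_id = character(), onset_day = integer(),
    prodrome_days = integer(), med_start_day = integer(),
    course_days = integer(), delta_symptom = numeric(),
    delta_pulse = numeric(), delta_spo2 = numeric(), med_type = character()
  )
}

# Additive shift trace for one signal over the study, given the episodes.
# The shift ramps linearly from 0 at onset_day to the full delta at
# med_start_day, stays at the full delta through the course, and returns to
# 0 afterwards.
episode_shift <- function(n_days, episodes, delta_col) {
  shift <- numeric(n_days)
  for (i in seq_len(nrow(episodes))) {
    e <- episodes[i, ]
    delta <- e[[delta_col]]
    if (e$prodrome_days > 0) {
      days <- e$onset_day:(e$med_start_day - 1L)
      shift[days + 1L] <- delta * (days - e$onset_day) / e$prodrome_days
    }
    course <- e$med_start_day:(e$med_start_day + e$course_days - 1L)
    course <- course[course < n_days]
    shift[course + 1L] <- delta
  }
  shift
}

# Round a continuous latent score into five ordinal items summing to it.
split_symptom_items <- function(total, item_max) {
  q <- total %/% 5L
  r <- total %% 5L
  items <- matrix(q, nrow = length(total), ncol = 5L)
  for (j in 1:5) {
    items[, j] <- items[, j] + as.integer(j <= r)
  }
  pmin(items, item_max)
}

#' Simulate one patient's daily telemonitoring series
#'
#' Generates one record per study day: five diary items and their total
#' symptom score, pulse rate, oxygen saturation, and standby-medication
#' flags. Stable days follow stationary lag-1 autoregressive noise around
#' the patient's baselines; during an exacerbation episode each signal
#' shifts by the episode's delta, ramping linearly over the prodrome and
#' held through the medication course. Values are clipped to physical
#' ranges (score within scale, pulse positive, SpO2 at most 100) and the
#' symptom score is rounded to the ordinal diary scale.
#'
#' @param profile one row of [sample_profiles()] output.
#' @param config the [cohort_config()].
#' @param seed optional integer; when given the series is reproducible in
#'   isolation.
#' @param episodes optional episode tibble to impose (otherwise episodes are
#'   drawn from `config$episodes`).
#' @return list with `records` (one row per day, all days completed) and
#'   `episodes` (the ground truth used).
#' @export
simulate_series <- function(profile, config, seed = NULL, episodes = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n_days <- config$n_days
  with_seed(seed, {
    if (is.null(episodes)) {
      episodes <- sample_episodes(profile, config)
    }
    shift_sym <- episode_shift(n_days, episodes, "delta_symptom")
    shift_pulse <- episode_shift(n_days, episodes, "delta_pulse")
    shift_spo2 <- episode_shift(n_days, episodes, "delta_spo2")

    latent_sym <- profile$baseline_symptom + shift_sym +
      ar1_noise(n_days, profile$noise_sd_symptom, profile$autocorr)
    pulse <- profile$baseline_pulse + shift_pulse +
      ar1_noise(n_days, profile$noise_sd_pulse, profile$autocorr)
    spo2 <- profile$baseline_spo2 - shift_spo2 +
      ar1_noise(n_days, profile$noise_sd_spo2, profile$autocorr)

    scale_max <- config$symptom_scale_max
    total <- as.integer(round(pmin(pmax(latent_sym, 0), scale_max)))
    items <- split_symptom_items(total, scale_max %/% 5L)
    pulse <- pmax(pulse, 1)
    spo2 <- pmin(pmax(spo2, 1), 100)

    med_abx <- logical(n_days)
    med_ster <- logical(n_days)
    for (i in seq_len(nrow(episodes))) {
      e <- episodes[i, ]
      course <- e$med_start_day:(e$med_start_day + e$course_days - 1L)
      course <- course[course < n_days] + 1L
      if (e$med_type %in% c("antibiotics", "both")) med_abx[course] <- TRUE
      if (e$med_type %in% c("steroids", "both")) med_ster[course] <- TRUE
    }

    records <- tibble::tibble(
      patient_id = profile$patient_id,
      day_index = 0:(n_days - 1L),
      date = day_to_date(0:(n_days - 1L), config$start_date),
      s1 = items[, 1], s2 = items[, 2], s3 = items[, 3],
      s4 = items[, 4], s5 = items[, 5],
      symptom_total = total,
      pulse_bpm = pulse,
      spo2_pct = spo2,
      med_antibiotics = med_abx,
      med_steroids = med_ster,
      completed = TRUE
    )
    list(records = records, episodes = episodes)
  })
}

#' Thin a complete series to a given compliance level
#'
#' Each day is independently retained with probability `compliance_prob`
#' (missing completely at random). On a removed day every diary item, the
#' symptom total, both vitals and the medication flags become missing and
#' `completed` becomes `FALSE`; the date and day index are kept so the
#' calendar stays intact.
#'
#' @param records a daily-record tibble as produced by [simulate_series()].
#' @param compliance_prob per-day probability of completing the diary and
#'   measurements, in `[0, 1]`.
#' @param seed optional integer for reproducibility.
#' @return the records tibble with non-completed days blanked.
#' @export
apply_missingness <- function(records, compliance_prob, seed = NULL) {
  assert_scalar_number(compliance_prob, "compliance_prob", lower = 0, upper = 1)
  with_seed(seed, {
    drop <- runif(nrow(records)) >= compliance_prob
    records$s1[drop] <- NA_integer_
    records$s2[drop] <- NA_integer_
    records$s3[drop] <- NA_integer_
    records$s4[drop] <- NA_integer_
    records$s5[drop] <- NA_integer_
    records$symptom_total[drop] <- NA_integer_
    records$pulse_bpm[drop] <- NA_real_
    records$spo2_pct[drop] <- NA_real_
    records$med_antibiotics[drop] <- NA
    records$med_steroids[drop] <- NA
    records$completed[drop] <- FALSE
    records
  })
}

#' Simulate a full synthetic telemonitoring cohort
#'
#' Samples patient profiles, simulates every patient's daily series with
#' exacerbation episodes, and applies per-patient missingness. All
#' randomness is fixed by `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return an object of class `copd_cohort`: a list with `config`,
#'   `profiles`, `records` (all patients' daily records) and `episodes`
#'   (ground-truth exacerbation episodes).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  profiles <- sample_profiles(config)
  seeds <- with_seed(config$seed + 1L, {
    matrix(sample.int(2147483646L, 2L * config$n_patients),
           ncol = 2L)
  })
  rec_list <- vector("list", config$n_patients)
  epi_list <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    sim <- simulate_series(profiles[i, ], config, seed = seeds[i, 1])
    rec_list[[i]] <- apply_missingness(sim$records,
                                       profiles$compliance_prob[i],
                                       seed = seeds[i, 2])
    epi_list[[i]] <- sim$episodes
  }
  structure(
    list(config = config,
         profiles = profiles,
         records = dplyr::bind_rows(rec_list),
         episodes = dplyr::bind_rows(epi_list)),
    class = "copd_cohort"
  )
}

#' @export
print.copd_cohort <- function(x, ...) {
  cat(sprintf(
    "<copd_cohort> %d patients x %d days (seed %d)\n",
    x$config$n_patients, x$config$n_days, x$config$seed
  ))
  cat(sprintf("  completed days: %d of %d (%.1f%%)\n",
              sum(x$records$completed), nrow(x$records),
              100 * mean(x$records$completed)))
  cat(sprintf("  ground-truth exacerbation episodes: %d\n", nrow(x$episodes)))
  invisible(x)
}
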