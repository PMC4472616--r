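# Fixture builders shared across the test files. All data is generated in
# code; nothing is read from disk.

# Minimal daily-record tibble for toy scenarios. Vector arguments are
# recycled to n_days; diary items are allocated from the total by integer
# division so the record invariants hold.
make_records <- function(n_days,
                         patient_id = "P1",
                         symptom = 10L,
                         pulse = 80,
                         spo2 = 95,
                         abx = FALSE,
                         ster = FALSE,
                         completed = TRUE,
                         start_date = as.Date("2014-01-01")) {
  symptom <- as.integer(rep_len(symptom, n_days))
  q <- symptom %/% 5L
  r <- symptom %% 5L
  items <- sapply(1:5, function(j) q + as.integer(j <= r))
  if (n_days == 1L) items <- matrix(items, nrow = 1L)
  rec <- tibble::tibble(
    patient_id = patient_id,
    day_index = 0:(n_days - 1L),
    date = start_date + 0:(n_days - 1L),
    s1 = items[, 1], s2 = items[, 2], s3 = items[, 3],
    s4 = items[, 4], s5 = items[, 5],
    symptom_total = symptom,
    pulse_bpm = rep_len(as.numeric(pulse), n_days),
    spo2_pct = rep_len(as.numeric(spo2), n_days),
    med_antibiotics = rep_len(abx, n_days),
    med_steroids = rep_len(ster, n_days),
    completed = rep_len(completed, n_days)
  )
  blank <- !rec$completed
  rec$s1[blank] <- NA_integer_; rec$s2[blank] <- NA_integer_
  rec$s3[blank] <- NA_integer_; rec$s4[blank] <- NA_integer_
  rec$s5[blank] <- NA_integer_
  rec$symptom_total[blank] <- NA_integer_
  rec$pulse_bpm[blank] <- NA_real_
  rec$spo2_pct[blank] <- NA_real_
  rec$med_antibiotics[blank] <- NA
  rec$med_steroids[blank] <- NA
  rec
}

# Toy alert tibble from (patient, day, signal) triplets.
make_alerts <- function(patient_id, day_index, signal = "pulse_bpm") {
  n <- max(length(patient_id), length(day_index), length(signal))
  tibble::tibble(
    patient_id = rep_len(patient_id, n),
    day_index = as.integer(rep_len(day_index, n)),
    signal = rep_len(signal, n),
    value = NA_real_, threshold = NA_real_,
    direction = "upper"
  )
}

make_events <- function(patient_id, start_day, end_day = start_day,
                        med_type = "antibiotics") {
  n <- max(length(patient_id), length(start_day))
  tibble::tibble(
    patient_id = rep_len(patient_id, n),
    start_day = as.integer(rep_len(start_day, n)),
    end_day = as.integer(rep_len(end_day, n)),
    med_type = rep_len(med_type, n)
  )
}

# Brute-force nearest-rank oracles: scan the observed values and count.
# Independent of the package's ranking formula.
oracle_quantile_upper <- function(values, p) {
  for (x in sort(values)) {
    if (mean(values <= x) >= p) return(x)
  }
  stop("unreachable")
}

oracle_quantile_lower <- function(values, p) {
  for (x in sort(values, decreasing = TRUE)) {
    if (mean(values >= x) >= p) return(x)
  }
  stop("unreachable")
}

# A profile row with every field pinned, for single-patient simulations.
fixed_profile <- function(patient_id = "P1",
                          baseline_symptom = 9.6,
                          baseline_pulse = 83.4,
                          baseline_spo2 = 93.8,
                          noise_sd_symptom = 2,
                          noise_sd_pulse = 12,
                          noise_sd_spo2 = 2.5,
                          autocorr = 0,
                          compliance_prob = 1,
                          exacerbation_rate = 0) {
  tibble::tibble(
    patient_id = patient_id,
    baseline_symptom = baseline_symptom,
    baseline_pulse = baseline_pulse,
    baseline_spo2 = baseline_spo2,
    noise_sd_symptom = noise_sd_symptom,
    noise_sd_pulse = noise_sd_pulse,
    noise_sd_spo2 = noise_sd_spo2,
    autocorr = autocorr,
    compliance_prob = compliance_prob,
    exacerbation_rate = exacerbation_rate
  )
}

# Deterministic cohort config for noiseless pipelines.
noiseless_config <- function(n_patients = 3, n_days = 120, seed = 1,
                             prodrome = 4, rate = 2) {
  cohort_config(
    n_patients = n_patients, n_days = n_days, seed = seed,
    profile_ranges = list(
      noise_sd_symptom = c(0, 0), noise_sd_pulse = c(0, 0),
      noise_sd_spo2 = c(0, 0), autocorr = c(0, 0),
      compliance_prob = c(1, 1), exacerbation_rate = c(rate, rate)
    ),
    episodes = episode_params(
      prodrome_days = c(prodrome, prodrome),
      delta_symptom = c(6, 6), delta_pulse = c(12, 12),
      delta_spo2 = c(4, 4)
    )
  )
}
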