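# Reading and writing cohorts as plain-text CSV.
#
# Layout of a cohort directory:
#   records.csv   one row per patient-day (missing values as empty cells,
#                 medication flags and `completed` as 0/1)
#   episodes.csv  ground-truth exacerbation episodes
#   profiles.csv  the sampled patient profiles
#   config.json   scalar generator settings, for provenance

records_col_types <- function() {
  readr::cols(
    patient_id = readr::col_character(),
    day_index = readr::col_integer(),
    date = readr::col_date(),
    s1 = readr::col_integer(), s2 = readr::col_integer(),
    s3 = readr::col_integer(), s4 = readr::col_integer(),
    s5 = readr::col_integer(),
    symptom_total = readr::col_integer(),
    pulse_bpm = readr::col_double(),
    spo2_pct = readr::col_double(),
    med_antibiotics = readr::col_integer(),
    med_steroids = readr::col_integer(),
    completed = readr::col_integer()
  )
}

#' Write a synthetic cohort to a directory of CSV files
#'
#' @param cohort a `copd_cohort` from [simulate_cohort()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "copd_cohort"))
  if (!dir.exists(path)) {
    dir.create(path, recursive = TRUE)
  }
  records <- cohort$records
  records$med_antibiotics <- as.integer(records$med_antibiotics)
  records$med_steroids <- as.integer(records$med_steroids)
  records$completed <- as.integer(records$completed)
  readr::write_csv(records, file.path(path, "records.csv"), na = "")
  readr::write_csv(cohort$episodes, file.path(path, "episodes.csv"), na = "")
  readr::write_csv(cohort$profiles, file.path(path, "profiles.csv"), na = "")
  cfg <- cohort$config
  # named vectors lose their names in JSON arrays; keep probabilities keyed
  cfg$episodes$med_type_probs <- as.list(cfg$episodes$med_type_probs)
  jsonlite::write_json(
    list(n_patients = cfg$n_patients, n_days = cfg$n_days, seed = cfg$seed,
         start_date = as.character(cfg$start_date),
         symptom_scale_max = cfg$symptom_scale_max,
         profile_ranges = cfg$profile_ranges,
         episodes = cfg$episodes),
    file.path(path, "config.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

# Stop with file, row and field of every offending record.
validate_records <- function(records, file, scale_max = 20) {
  fail <- function(rows, field, why) {
    if (!any(rows)) return(invisible())
    # +1 for the header line
    lines <- paste(which(rows) + 1L, collapse = ", ")
    abort(sprintf("%s: invalid `%s` (%s) at line(s) %s.",
                  file, field, why, lines))
  }
  item_max <- scale_max %/% 5L
  for (it in c("s1", "s2", "s3", "s4", "s5")) {
    v <- records[[it]]
    fail(!is.na(v) & (v < 0 | v > item_max), it,
         sprintf("outside 0..%d", item_max))
  }
  fail(!is.na(records$symptom_total) &
         (records$symptom_total < 0 | records$symptom_total > scale_max),
       "symptom_total", sprintf("outside 0..%d", scale_max))
  fail(!is.na(records$pulse_bpm) & records$pulse_bpm <= 0,
       "pulse_bpm", "must be positive")
  fail(!is.na(records$spo2_pct) &
         (records$spo2_pct <= 0 | records$spo2_pct > 100),
       "spo2_pct", "must be in (0, 100]")
  fail(is.na(records$day_index), "day_index", "missing")
  fail(is.na(records$patient_id) | records$patient_id == "",
       "patient_id", "missing")
  # per-patient: non-empty, contiguous day indices from 0
  split_idx <- split(seq_len(nrow(records)), records$patient_id)
  for (pid in names(split_idx)) {
    idx <- split_idx[[pid]]
    days <- sort(records$day_index[idx])
    if (length(days) == 0L) {
      abort(sprintf("%s: patient %s has an empty series.", file, pid))
    }
    if (!identical(as.integer(days), 0:(length(days) - 1L))) {
      abort(sprintf(
        "%s: patient %s day indices are not contiguous from 0.", file, pid))
    }
  }
  invisible(records)
}

#' Read a cohort written by [write_cohort()]
#'
#' Validates every row (vitals within physical ranges, diary items on scale,
#' contiguous day indices per patient) and reports the file, line and field
#' of anything malformed. `read_cohort(write_cohort(x)) ` reproduces `x`'s
#' records, episodes and profiles exactly, including missingness markers.
#'
#' @param path directory produced by [write_cohort()].
#' @return a `copd_cohort` (with `config` rebuilt from `config.json`).
#' @export
read_cohort <- function(path) {
  rec_file <- file.path(path, "records.csv")
  if (!file.exists(rec_file)) {
    abort(sprintf("no records.csv under '%s'.", path))
  }
  cfg_file <- file.path(path, "config.json")
  cfg <- if (file.exists(cfg_file)) jsonlite::read_json(cfg_file) else NULL
  scale_max <- if (is.null(cfg)) 20L else as.integer(cfg$symptom_scale_max)

  records <- readr::read_csv(rec_file, col_types = records_col_types(),
                             na = "", progress = FALSE)
  if (nrow(records) == 0L) {
    abort(sprintf("%s: cohort has no records.", rec_file))
  }
  probs <- readr::problems(records)
  if (nrow(probs) > 0L) {
    p <- probs[1, ]
    abort(sprintf("%s: unparseable value at line %d, column %d (%s).",
                  rec_file, p$row, p$col, p$expected))
  }
  validate_records(records, rec_file, scale_max = scale_max)
  records$med_antibiotics <- as.logical(records$med_antibiotics)
  records$med_steroids <- as.logical(records$med_steroids)
  records$completed <- as.logical(records$completed)

  epi_file <- file.path(path, "episodes.csv")
  episodes <- if (file.exists(epi_file)) {
    readr::read_csv(epi_file, col_types = readr::cols(
      patient_id = readr::col_character(),
      onset_day = readr::col_integer(),
      prodrome_days = readr::col_integer(),
      med_start_day = readr::col_integer(),
      course_days = readr::col_integer(),
      delta_symptom = readr::col_double(),
      delta_pulse = readr::col_double(),
      delta_spo2 = readr::col_double(),
      med_type = readr::col_character()
    ), na = "", progress = FALSE)
  } else {
    empty_episodes()
  }

  prof_file <- file.path(path, "profiles.csv")
  profiles <- if (file.exists(prof_file)) {
    readr::read_csv(prof_file, col_types = readr::cols(
      patient_id = readr::col_character(),
      .default = readr::col_double()
    ), na = "", progress = FALSE)
  } else {
    NULL
  }

  config <- if (!is.null(cfg)) {
    cohort_config(
      n_patients = cfg$n_patients, n_days = cfg$n_days, seed = cfg$seed,
      profile_ranges = lapply(cfg$profile_ranges, unlist),
      episodes = do.call(episode_params, utils::modifyList(
        lapply(cfg$episodes, unlist), list())),
      start_date = cfg$start_date,
      symptom_scale_max = cfg$symptom_scale_max
    )
  } else {
    NULL
  }

  structure(
    list(config = config, profiles = profiles,
         records = records, episodes = episodes),
    class = "copd_cohort"
  )
}
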