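#' Total symptom score from the five diary items
#'
#' The daily diary asks about general well-being, cough, sputum quantity,
#' sputum colour and breathlessness, each answered on an ordinal scale from
#' 0 to `item_max`. The daily symptom score is their sum; if any item is
#' missing the total is missing.
#'
#' @param items numeric vector of five item responses, or a data frame /
#'   matrix with five item columns (one row per day).
#' @param item_max maximum of each item's scale (default 4, total 0--20).
#' @return a single total, or a vector of totals for row-wise input.
#' @examples
#' compute_symptom_total(c(2, 1, 3, 1, 2)) # 9
#' @export
compute_symptom_total <- function(items, item_max = 4) {
  if (is.data.frame(items) || is.matrix(items)) {
    m <- as.matrix(items)
    if (ncol(m) != 5L) {
      abort("`items` must have exactly five columns.")
    }
    return(apply(m, 1L, compute_symptom_total, item_max = item_max))
  }
  if (length(items) != 5L) {
    abort("`items` must have exactly five responses.")
  }
  bad <- !is.na(items) & (items < 0 | items > item_max |
                            items != floor(items))
  if (any(bad)) {
    abort(sprintf("diary item out of the 0..%d scale: %s",
                  item_max, paste(items[bad], collapse = ", ")))
  }
  if (anyNA(items)) {
    return(NA_integer_)
  }
  as.integer(sum(items))
}

#' Extract exacerbation events from medication diaries
#'
#' An exacerbation event is deemed to occur when a patient initiates
#' standby medication: a day on which antibiotics and/or oral steroids are
#' taken, with no medication day in the preceding `merge_gap_days` days.
#' Subsequent medication days separated by gaps shorter than
#' `merge_gap_days` belong to the same event, so a skipped diary inside a
#' course does not split it. Days with a missing medication diary are
#' treated as non-medication days. The event's `med_type` is
#' `"antibiotics"`, `"steroids"`, or `"both"` according to which drugs
#' appear anywhere within the event.
#'
#' @param records daily-record tibble (one or many patients).
#' @param merge_gap_days medication-free days required to start a new event
#'   (default 7).
#' @return tibble of events: `patient_id`, `start_day` (first medication
#'   day), `end_day` (last medication day of the run), `med_type`.
#' @export
extract_events <- function(records, merge_gap_days = 7) {
  assert_scalar_number(merge_gap_days, "merge_gap_days", lower = 1,
                       integerish = TRUE)
  out <- records |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(~ extract_events_one(.x, merge_gap_days)) |>
    dplyr::ungroup()
  if (nrow(out) == 0L) {
    return(tibble::tibble(patient_id = character(), start_day = integer(),
                          end_day = integer(), med_type = character()))
  }
  out[, c("patient_id", "start_day", "end_day", "med_type")]
}

extract_events_one <- function(records, merge_gap_days) {
  records <- dplyr::arrange(records, .data$day_index)
  abx <- records$med_antibiotics %in% TRUE
  ster <- records$med_steroids %in% TRUE
  med_days <- records$day_index[abx | ster]
  if (length(med_days) == 0L) {
    return(tibble::tibble(start_day = integer(), end_day = integer(),
                          med_type = character()))
  }
  # split medication days into events wherever the gap exceeds the merge gap
  brk <- c(TRUE, diff(med_days) > merge_gap_days)
  grp <- cumsum(brk)
  starts <- tapply(med_days, grp, min)
  ends <- tapply(med_days, grp, max)
  med_type <- vapply(split(med_days, grp), function(days) {
    has_abx <- any(abx[records$day_index %in% days])
    has_ster <- any(ster[records$day_index %in% days])
    if (has_abx && has_ster) "both" else if (has_abx) "antibiotics" else "steroids"
  }, character(1))
  tibble::tibble(start_day = as.integer(starts),
                 end_day = as.integer(ends),
                 med_type = unname(med_type))
}
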