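# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (integerish && x != floor(x)) {
    abort(sprintf("`%s` must be an integer (got %s).", name, format(x)))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s] (got %s).",
                  name, format(lower), format(upper), format(x)))
  }
  invisible(x)
}

assert_range <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 2L || anyNA(x) || x[1] > x[2]) {
    abort(sprintf("`%s` must be a numeric c(min, max) with min <= max.", name))
  }
  if (x[1] < lower || x[2] > upper) {
    abort(sprintf("`%s` must lie within [%s, %s] (got [%s, %s]).",
                  name, format(lower), format(upper),
                  format(x[1]), format(x[2])))
  }
  invisible(x)
}

#' Nearest-rank quantile of a sample
#'
#' The quantile convention used throughout the package, for alert thresholds
#' and for usage-duration percentiles alike. For `direction = "upper"` it
#' returns the smallest sample value whose empirical CDF reaches `p`
#' (the classical nearest-rank quantile, `sorted[ceiling(n * p)]`). For
#' `direction = "lower"` it returns the mirror image: the largest sample value
#' `v` such that at least a fraction `p` of the sample is `>= v`. Both
#' always return an observed sample value.
#'
#' @param values numeric vector; `NA`s are dropped.
#' @param p probability in (0, 1].
#' @param direction `"upper"` (default) or `"lower"`.
#' @return a single number, an element of `values`.
#' @examples
#' nearest_rank_quantile(1:100, 0.95)                      # 95
#' nearest_rank_quantile(1:100, 0.95, direction = "lower") # 6
#' @export
nearest_rank_quantile <- function(values, p, direction = c("upper", "lower")) {
  direction <- match.arg(direction)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) {
    abort("`values` must contain at least one non-missing number.")
  }
  assert_scalar_number(p, "p", lower = 0, upper = 1)
  if (p <= 0) {
    abort("`p` must be strictly positive.")
  }
  sv <- sort(values)
  k <- ceiling(n * p)
  if (direction == "upper") sv[k] else sv[n - k + 1L]
}

# Days elapsed -> ISO dates for a series starting at `start_date` (day 0).
day_to_date <- function(day_index, start_date) {
  as.Date(start_date) + as.integer(day_index)
}
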