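#' Threshold-derivation panel for one patient and signal
#'
#' Reproduces the standard display of the personalized alerting method:
#' the daily signal trace with the run-in shaded and the threshold drawn,
#' alongside the training-data histogram and empirical CDF with the
#' centile and threshold marked.
#'
#' @param records daily records of a single patient.
#' @param thresholds threshold tibble from [fit_thresholds()].
#' @param signal which signal to plot.
#' @return a patchwork/ggplot object.
#' @export
plot_threshold_panel <- function(records, thresholds,
                                 signal = c("symptom_total", "pulse_bpm",
                                            "spo2_pct")) {
  signal <- match.arg(signal)
  pid <- unique(records$patient_id)
  if (length(pid) != 1L) {
    abort("`records` must belong to a single patient.")
  }
  model <- thresholds[thresholds$patient_id == pid &
                        thresholds$signal == signal, ]
  if (nrow(model) != 1L) {
    abort(sprintf("no fitted threshold for patient %s signal %s.",
                  pid, signal))
  }
  train <- records[records$day_index <= model$train_end_day, ]
  values <- train[[signal]][!is.na(train[[signal]])]
  cdf <- empirical_cdf(values)
  p_target <- model$centile / 100

  trace <- ggplot2::ggplot(records,
                           ggplot2::aes(x = .data$day_index,
                                        y = .data[[signal]])) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = model$train_end_day,
                      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "grey40") +
    ggplot2::geom_line(na.rm = TRUE, colour = "grey30") +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = model$threshold, colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = "study day", y = signal,
                  title = sprintf("%s - %s (threshold %.1f, %s %gth centile)",
                                  pid, signal, model$threshold,
                                  model$direction, model$centile)) +
    ggplot2::theme_minimal()

  hist <- ggplot2::ggplot(data.frame(value = values),
                          ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 15, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = model$threshold, colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = signal, y = "count", title = "run-in histogram") +
    ggplot2::theme_minimal()

  grid <- seq(min(values), max(values), length.out = 256)
  cdf_df <- data.frame(value = grid, F = cdf(grid))
  p_line <- if (model$direction == "upper") p_target else 1 - p_target
  cdf_plot <- ggplot2::ggplot(cdf_df,
                              ggplot2::aes(x = .data$value, y = .data$F)) +
    ggplot2::geom_step(colour = "grey30") +
    ggplot2::geom_hline(yintercept = p_line, colour = "grey60",
                        linetype = 3) +
    ggplot2::geom_vline(xintercept = model$threshold, colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = signal, y = "CDF", title = "run-in CDF") +
    ggplot2::theme_minimal()

  patchwork::wrap_plots(
    trace,
    patchwork::wrap_plots(hist, cdf_plot, ncol = 2),
    ncol = 1
  )
}
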