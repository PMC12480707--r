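#' Plot hourly profiles of one metric across subjects
#'
#' @param hourly Long hourly matrix from [hourly_aggregate()].
#' @param metric Metric name to plot.
#' @return A ggplot.
#' @export
plot_hourly_profile <- function(hourly, metric) {
  d <- hourly[hourly$metric == metric & is.finite(hourly$value), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hour, y = .data$value,
                                  group = .data$subject_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "line", colour = "firebrick",
                          linewidth = 1) +
    ggplot2::labs(x = "clock hour", y = metric,
                  title = paste("Hourly profile:", metric)) +
    ggplot2::theme_minimal()
}

#' Plot the distribution of fitted acrophases
#'
#' Histogram of per-subject peak clock times for each metric, optionally
#' split by group.
#'
#' @param fits Cosinor fit table from [fit_cohort()] or [run_pipeline()].
#' @param by Optional grouping column name (e.g. `"sex"`).
#' @return A ggplot.
#' @export
plot_acrophases <- function(fits, by = NULL) {
  d <- fits[is.finite(fits$acro_clock_h), ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$acro_clock_h))
  p <- if (is.null(by)) p + ggplot2::geom_histogram(binwidth = 1,
                                                    boundary = 0)
       else p + ggplot2::geom_histogram(
         ggplot2::aes(fill = .data[[by]]), binwidth = 1, boundary = 0,
         position = "identity", alpha = 0.6)
  p + ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_x_continuous(limits = c(0, 24),
                                breaks = seq(0, 24, 6)) +
    ggplot2::labs(x = "acrophase (clock hour)", y = "subjects") +
    ggplot2::theme_minimal()
}
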