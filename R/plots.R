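# Best-effort plotting conveniences; the CSV tables are the pipeline's
# contract, these are for quick inspection.

#' Plot an aggregated population curve
#'
#' Mean over replicate summaries with an SD ribbon, one line per condition —
#' the conventional display of confinement-ratio decay and MSD curves.
#'
#' @param agg Data frame from the pipeline's aggregation: columns
#'   `condition`, `abscissa`, `mean`, `sd`.
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_aggregated_curve <- function(agg, xlab = "time (s)", ylab = "value") {
  stopifnot(all(c("condition", "abscissa", "mean", "sd") %in% names(agg)))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$abscissa, y = .data$mean,
                                    color = .data$condition,
                                    fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_classic()
}

#' SuperPlot-style scatter of per-cell values with replicate medians
#'
#' Per-cell values jittered within condition, replicate medians as large
#' circles (the values the statistics run on), and the mean of medians as a
#' crossbar.
#'
#' @param df Long data frame `condition`, `replicate`, `value`.
#' @param ylab Axis label.
#' @return A ggplot object.
#' @export
plot_superplot <- function(df, ylab = "value") {
  stopifnot(all(c("condition", "replicate", "value") %in% names(df)))
  meds <- replicate_medians(df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$value)) +
    ggplot2::geom_jitter(ggplot2::aes(color = factor(.data$replicate)),
                         width = 0.25, alpha = 0.4, size = 0.8) +
    ggplot2::geom_point(data = meds,
                        ggplot2::aes(y = .data$median,
                                     fill = factor(.data$replicate)),
                        shape = 21, size = 3) +
    ggplot2::stat_summary(data = meds, ggplot2::aes(y = .data$median),
                          fun = mean, geom = "crossbar", width = 0.5,
                          linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = ylab, color = "replicate",
                  fill = "replicate") +
    ggplot2::theme_classic()
}
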