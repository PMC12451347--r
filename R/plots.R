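#' Plot mean quality metrics across observation windows
#'
#' Mean with an SD ribbon-style errorbar per window, in the layout used
#' for treatment-quality figures (window 0 = Ramadan).
#'
#' @param quality Tibble from [window_quality()].
#' @param metric Metric column name (string).
#' @return A ggplot.
#' @export
plot_window_quality <- function(quality, metric = "ttr") {
  d <- summarize_metric(quality, metric)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$window, y = .data$mean)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted",
                        colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.15) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Observation window (0 = Ramadan)",
                  y = paste0(metric, " (mean ± SD)")) +
    ggplot2::theme_minimal()
}

#' Plot per-window 30-day cumulative incidence
#'
#' @param incidence Tibble from [window_incidence()].
#' @param outcome Outcome name to display (default `"composite"`).
#' @return A ggplot.
#' @export
plot_window_incidence <- function(incidence, outcome = "composite") {
  d <- filter(incidence, .data$outcome == .env$outcome)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$window,
                                  y = .data$cuminc_per_1000)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$cuminc_low,
                                          ymax = .data$cuminc_high)) +
    ggplot2::labs(x = "Observation window (0 = Ramadan)",
                  y = "30-day cumulative incidence per 1000 (95% CI)",
                  title = outcome) +
    ggplot2::theme_minimal()
}
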