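# ggplot2 views of the main result types.

#' @export
autoplot.pooled_response <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from stimulus onset (s)",
                  y = expression(Delta * F / F[0]),
                  title = "Pooled stimulus-aligned response (mean ± SD)")
}

#' Plot dF/F0 traces per neuron
#'
#' @param trace Normalized trace tibble from [normalize_trace()].
#' @return A ggplot.
#' @export
plot_traces <- function(trace) {
  onset <- attr(trace, "stimulus_onset_frame", exact = TRUE)
  dur <- attr(trace, "stimulus_duration_frames", exact = TRUE)
  dt <- attr(trace, "frame_interval_s", exact = TRUE)
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$time_s, y = .data$dff,
                                      colour = .data$neuron_id)) +
    ggplot2::geom_line() +
    ggplot2::annotate("rect", xmin = onset * dt, xmax = (onset + dur) * dt,
                      ymin = -Inf, ymax = Inf, alpha = 0.1, fill = "red") +
    ggplot2::facet_wrap(~movie_id) +
    ggplot2::labs(x = "time (s)", y = expression(Delta * F / F[0]),
                  colour = "neuron")
}

#' Stacked response-class fraction bars per condition
#'
#' @param fractions Tibble from [summarize_calls()].
#' @return A ggplot.
#' @export
plot_fraction_bars <- function(fractions) {
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = .data$condition, y = .data$fraction,
                               fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(high = "#2ca02c",
                                          moderate = "#ffbf00",
                                          absent = "#d62728")) +
    ggplot2::labs(x = NULL, y = "fraction of neurons", fill = "response")
}

#' Plot an estimated shift series
#'
#' @param shifts Tibble from [register_movie()].
#' @return A ggplot.
#' @export
plot_shifts <- function(shifts) {
  long <- tidyr::pivot_longer(shifts, c("dy", "dx"), names_to = "axis",
                              values_to = "shift_px")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$shift_px,
                                     colour = .data$axis)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "frame", y = "estimated shift (px)")
}
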