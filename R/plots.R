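#' Plot multichannel oscillator waveforms
#'
#' @param object An `onn_waveforms` tibble.
#' @param window Optional length-2 time window (s) to display.
#' @param ... Unused.
#' @return A ggplot object (voltage vs time, one colour per channel).
#' @method autoplot onn_waveforms
#' @export
autoplot.onn_waveforms <- function(object, window = NULL, ...) {
  if (!is.null(window)) object <- clip_window(object, window)
  long <- tidyr::pivot_longer(as_tibble(object), -"time_s",
                              names_to = "channel", values_to = "voltage")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s * 1e6, y = .data$voltage,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (µs)", y = "output voltage (V)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the 2-D projections of a limit cycle
#'
#' @param object A [limit_cycle()] tibble.
#' @param ... Unused.
#' @return A ggplot object, one panel per projection plane.
#' @method autoplot limit_cycle
#' @export
autoplot.limit_cycle <- function(object, ...) {
  proj <- limit_cycle_projections(object)
  ggplot2::ggplot(proj, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(alpha = 0.6, linewidth = 0.3) +
    ggplot2::facet_wrap(~plane) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "voltage (V)", y = "voltage (V)") +
    ggplot2::theme_minimal()
}

#' Plot decision-network activities over time
#'
#' @param object A `dm_run`.
#' @param ... Unused.
#' @return A ggplot object of each neuron's activity; the decision
#'   threshold is drawn as a dashed line.
#' @method autoplot dm_run
#' @export
autoplot.dm_run <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time, y = .data$r, colour = .data$neuron)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$params$r_dec, linetype = "dashed") +
    ggplot2::labs(x = "decision-network time", y = "activity r", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a phase pattern as a clock diagram
#'
#' @param object A [phase_pattern()].
#' @param ... Unused.
#' @return A ggplot object: one radial spoke per channel.
#' @method autoplot phase_pattern
#' @export
autoplot.phase_pattern <- function(object, ...) {
  df <- tibble(channel = object$channel, phase = object$phase_deg)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, xend = .data$phase,
                                   y = 0, yend = 1, colour = .data$channel)) +
    ggplot2::geom_segment(linewidth = 1) +
    ggplot2::coord_polar() +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    ggplot2::labs(x = "phase (deg)", y = NULL, colour = NULL,
                  title = sprintf("common frequency %.1f kHz",
                                  attr(object, "common_frequency") / 1e3)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
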