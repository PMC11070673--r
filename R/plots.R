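# ggplot2 displays for the main result types.

#' Plot direction-resolved activity vectors
#'
#' @param av tibble from [activity_vectors()].
#' @return a ggplot object.
#' @export
plot_activity_vectors <- function(av) {
  ggplot2::ggplot(av, ggplot2::aes(x = .data$bin, y = .data$rate_hz,
                                   colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(x = "position bin (1 = reward zone, 10 = trigger zone)",
                  y = "firing rate (Hz)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot unique contributions per variable
#'
#' Per-neuron delta r^2 by variable, with significant neurons highlighted.
#'
#' @param object an `encoding_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.encoding_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$variable, y = .data$delta_r2)) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$significant),
                         width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = expression(Delta * r^2),
                  colour = "significant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot gamma-burst rates by traversal direction
#'
#' @param rates per-traversal rates from [detect_gamma_bursts()].
#' @return a ggplot object.
#' @export
plot_burst_rates <- function(rates) {
  ggplot2::ggplot(rates, ggplot2::aes(x = .data$direction,
                                      y = .data$bursts_per_s)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          linewidth = 0.3, colour = "red") +
    ggplot2::labs(x = NULL, y = "gamma bursts / s") +
    ggplot2::theme_minimal()
}

#' Plot relative LFP power spectra by direction
#'
#' @param spec tibble from [traversal_spectrum()].
#' @return a ggplot object.
#' @export
plot_traversal_spectrum <- function(spec) {
  ggplot2::ggplot(spec, ggplot2::aes(x = .data$freq_hz,
                                     y = .data$rel_power,
                                     colour = .data$direction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "relative power",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
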