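#' Plot a frequency-response table
#'
#' Gain and phase versus frequency (log-scaled axis) with standard-error
#' bars, in the layout the field uses for VOR Bode summaries.
#'
#' @param object A `vp_freq_response` from [summarize_response()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vp_freq_response <- function(object, ...) {
  long <- tibble::tibble(
    frequency_hz = rep(object$frequency_hz, 2),
    panel = rep(c("gain (eye/head)", "phase (deg)"), each = nrow(object)),
    value = c(object$mean_gain, object$mean_phase_deg),
    se = c(object$se_gain, object$se_phase_deg)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frequency_hz, y = .data$value)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$se,
                                        ymax = .data$value + .data$se),
                           width = 0.05) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)", y = NULL,
                  title = "VOR frequency response") +
    ggplot2::theme_minimal()
}

#' Plot a mapping's linear-stage Bode response
#'
#' @param mapping A [build_mapping()] object.
#' @param frequencies Frequencies (Hz) to evaluate.
#' @return A ggplot object.
#' @export
plot_mapping_response <- function(mapping,
                                  frequencies = 10^seq(log10(0.2), log10(20),
                                                       length.out = 60)) {
  fr <- mapping_frequency_response(mapping, frequencies)
  long <- tidyr::pivot_longer(fr, -"frequency_hz",
                              names_to = "panel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$frequency_hz, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)", y = NULL,
                  title = paste0(mapping$kind, " mapping (x",
                                 mapping$gain_multiplier, ")")) +
    ggplot2::theme_minimal()
}

#' Plot peak eye velocity against peak stimulation rate
#'
#' Scatter of the paired maxima produced by [peak_velocity_curve()], the
#' model-side analogue of the stimulation-rate/eye-velocity operating plot.
#'
#' @param curve Output of [peak_velocity_curve()].
#' @return A ggplot object.
#' @export
plot_peak_velocity <- function(curve) {
  stopifnot(all(c("max_rate_pps", "max_eye_vel_dps") %in% names(curve)))
  aes <- if ("frequency_hz" %in% names(curve)) {
    ggplot2::aes(.data$max_rate_pps, .data$max_eye_vel_dps,
                 colour = factor(.data$frequency_hz))
  } else {
    ggplot2::aes(.data$max_rate_pps, .data$max_eye_vel_dps)
  }
  ggplot2::ggplot(curve, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "maximum stimulation rate (pps)",
                  y = "maximum eye velocity (deg/s)",
                  colour = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a fitted transfer function against its fitting data
#'
#' @param object A `vp_tf` from [fit_rational_tf()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vp_tf <- function(object, ...) {
  f <- object$response$frequency_hz
  grid <- 10^seq(log10(min(f)), log10(max(f)), length.out = 80)
  fit <- tf_frequency_response(object, grid)
  dat <- object$response
  long_fit <- tibble::tibble(
    frequency_hz = rep(grid, 2),
    panel = rep(c("gain", "phase (deg)"), each = length(grid)),
    value = c(fit$gain, fit$phase_deg)
  )
  long_dat <- tibble::tibble(
    frequency_hz = rep(f, 2),
    panel = rep(c("gain", "phase (deg)"), each = length(f)),
    value = c(dat$gain, dat$phase_deg)
  )
  ggplot2::ggplot(long_fit, ggplot2::aes(.data$frequency_hz, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = long_dat, colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)", y = NULL,
                  title = "rational transfer-function fit") +
    ggplot2::theme_minimal()
}
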