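#' Tidy a fitted rational transfer function
#'
#' @param x A `vp_tf` from [fit_rational_tf()].
#' @param ... Unused.
#' @return A tibble with one row per zero/pole: `term`, `real`, `imaginary`,
#'   `frequency_hz` (natural frequency `|root| / 2 pi`).
#' @export
tidy.vp_tf <- function(x, ...) {
  roots <- c(x$zeros, x$poles)
  tibble::tibble(
    term = c(if (length(x$zeros)) paste0("zero_", seq_along(x$zeros)),
             if (length(x$poles)) paste0("pole_", seq_along(x$poles))),
    real = Re(roots),
    imaginary = Im(roots),
    frequency_hz = Mod(roots) / (2 * pi)
  )
}

#' @describeIn tidy.vp_tf One-row model summary: gain, delay, orders,
#'   convergence, and the VAF of the fit evaluated at the fitting
#'   frequencies.
#' @export
glance.vp_tf <- function(x, ...) {
  pred <- tf_frequency_response(x, x$response$frequency_hz)$response
  obs <- x$response$gain * exp(1i * x$response$phase_deg * pi / 180)
  resid <- Mod(obs - pred)
  tibble::tibble(
    gain = Re(x$gain),
    delay_s = x$delay,
    n_zeros = x$n_zeros,
    n_poles = x$n_poles,
    converged = x$converged,
    iterations = x$iterations,
    rms_residual = sqrt(mean(resid^2))
  )
}

#' Tidy an efficacy fit
#'
#' @param x A `vp_efficacy_fit` from [estimate_efficacy()].
#' @param ... Unused.
#' @return Per-condition predicted vs observed peak velocities.
#' @export
tidy.vp_efficacy_fit <- function(x, ...) {
  x$table
}

#' @describeIn tidy.vp_efficacy_fit One-row summary: `efficacy`,
#'   `depression_variant`, `objective`, `n_conditions`.
#' @export
glance.vp_efficacy_fit <- function(x, ...) {
  tibble::tibble(
    efficacy = x$efficacy,
    depression_variant = x$depression_variant,
    objective = x$objective,
    n_conditions = nrow(x$table)
  )
}
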