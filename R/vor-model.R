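#' VOR pathway model parameters
#'
#' Parameters of the control-systems forward model that maps afferent firing
#' rate to slow-phase eye velocity. The chain is: stimulation efficacy
#' (fraction of pulses that evoke an afferent spike), a first-order high-pass
#' "adaptation" filter on the afferent modulation, the vestibular-nucleus
#' velocity-storage stage `TVN(s) = -gVOR (s Tc + 1) TVOR / (Tc (s TVOR + 1))`,
#' the neural-integrator/plant combination, which reduces to
#' `exp(-s tau) / (s Te2 + 1)` after the shared time constant Te1 cancels, and
#' an optional central-pathway depression factor. The sign of the
#' vestibular-nucleus stage is negative: positive ("on"-direction) afferent
#' modulation drives contralaterally directed, compensatory eye velocity.
#'
#' Two presets bundle the plant and adaptation settings used for the two
#' implanted animals the model emulates: `monkey_G_like` (`t_e2 = 0.025` s,
#' `hp_cutoff = 3.5` Hz) and `monkey_Y_like` (`t_e2 = 0.008` s,
#' `hp_cutoff = 0.2` Hz).
#'
#' If `gvor` is `NULL` it is calibrated with [calibrate_gvor()] so that the
#' natural (canal-driven) VOR has unit gain at 2 Hz.
#'
#' @param preset `"monkey_G_like"` or `"monkey_Y_like"`.
#' @param gvor VOR gain (dimensionless), or `NULL` to calibrate.
#' @param t_vor Velocity-storage time constant (s).
#' @param t_c Canal time constant (s).
#' @param tau Pathway delay (s).
#' @param t_e2 Oculomotor-plant time constant (s); preset-dependent default.
#' @param hp_cutoff Adaptation high-pass cutoff (Hz); preset-dependent default.
#'   Use 0 to disable the filter.
#' @param hp_order Order of the adaptation high-pass (first order by default).
#' @param efficacy Stimulation efficacy in (0, 1].
#' @param depression Central-pathway reduction fraction in \[0, 1), e.g. 0.17.
#' @param r0 Baseline pulse rate (pps) about which modulation is measured.
#' @return An object of class `vp_vor_params`.
#' @examples
#' vor_params("monkey_G_like", efficacy = 0.28)
#' @export
vor_params <- function(preset = c("monkey_G_like", "monkey_Y_like"),
                       gvor = NULL, t_vor = 16, t_c = 5.7, tau = 0.006,
                       t_e2 = NULL, hp_cutoff = NULL, hp_order = 1L,
                       efficacy = 1, depression = 0, r0 = 150) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    monkey_G_like = list(t_e2 = 0.025, hp_cutoff = 3.5),
    monkey_Y_like = list(t_e2 = 0.008, hp_cutoff = 0.2)
  )
  t_e2 <- t_e2 %||% defaults$t_e2
  hp_cutoff <- hp_cutoff %||% defaults$hp_cutoff
  stopifnot(t_vor > 0, t_c > 0, tau >= 0, t_e2 > 0, hp_cutoff >= 0,
            hp_order >= 1L)
  if (!is.numeric(efficacy) || efficacy <= 0 || efficacy > 1) {
    stop("`efficacy` must be in (0, 1]", call. = FALSE)
  }
  if (depression < 0 || depression >= 1) {
    stop("`depression` must be in [0, 1)", call. = FALSE)
  }
  p <- structure(
    list(preset = preset, gvor = gvor, t_vor = t_vor, t_c = t_c, tau = tau,
         t_e2 = t_e2, hp_cutoff = hp_cutoff, hp_order = as.integer(hp_order),
         efficacy = efficacy, depression = depression, r0 = r0),
    class = "vp_vor_params"
  )
  if (is.null(p$gvor)) p$gvor <- calibrate_gvor(p)
  p
}

#' @export
print.vp_vor_params <- function(x, ...) {
  cat("<vp_vor_params> preset:", x$preset, "\n")
  cat("  gVOR:", signif(x$gvor, 5), " TVOR:", x$t_vor, "s  Tc:", x$t_c,
      "s  tau:", x$tau, "s  Te2:", x$t_e2, "s\n")
  cat("  adaptation high-pass:", x$hp_cutoff, "Hz (order", x$hp_order, ")\n")
  cat("  efficacy:", x$efficacy, " depression:", x$depression,
      " baseline:", x$r0, "pps\n")
  invisible(x)
}

#' Calibrate the VOR gain constant
#'
#' Solves for `gVOR` so that the natural VOR — semicircular-canal torsion-
#' pendulum dynamics `s Tc / (s Tc + 1)` acting on head velocity, followed by
#' the central chain — has unit gain at 2 Hz ("perfect compensation"). The
#' canal pole cancels against the velocity-storage zero, leaving
#' `|gVOR TVOR s / ((s TVOR + 1)(s Te2 + 1))| = 1` at `s = i 4 pi`; only the
#' magnitude is constrained (phase is left free).
#'
#' @param params A [vor_params()] object (its `gvor` field is ignored).
#' @return The calibrated gain (dimensionless).
#' @examples
#' calibrate_gvor(vor_params("monkey_G_like"))  # about 1.048
#' @export
calibrate_gvor <- function(params) {
  stopifnot(inherits(params, "vp_vor_params"))
  w <- 2 * pi * 2
  sqrt((w * params$t_vor)^2 + 1) * sqrt((w * params$t_e2)^2 + 1) /
    (params$t_vor * w)
}

#' Model the afferent firing rate evoked by prosthetic stimulation
#'
#' Converts a commanded pulse-rate series into the modeled afferent response.
#' The absolute afferent rate is `efficacy * final_rate` (e.g. 500 pps at 28%
#' efficacy translates to 140 spikes/s); the modulation about baseline,
#' `efficacy * (final_rate - r0)`, is passed through the first-order
#' adaptation high-pass (cutoff `hp_cutoff`), which reproduces the high-pass
#' behaviour of the prosthesis-evoked VOR at low frequencies. Efficacy and the
#' linear filter commute, so the order of the two steps is immaterial.
#'
#' @param rates Output of [encode_head_velocity()] (columns `time_s`,
#'   `final_rate_pps`).
#' @param params A [vor_params()] object.
#' @param asymmetry Scale factor applied to negative ("off"-direction) afferent
#'   modulation before filtering; 1 = symmetric. Used by the synthetic-data
#'   generator to emulate unilateral stimulation.
#' @return The input tibble with added columns `afferent_rate_sps` (absolute,
#'   unfiltered) and `afferent_mod_sps` (high-passed modulation about
#'   baseline).
#' @export
pulses_to_afferent_rate <- function(rates, params, asymmetry = 1) {
  stopifnot(inherits(params, "vp_vor_params"), is.data.frame(rates),
            all(c("time_s", "final_rate_pps") %in% names(rates)))
  fs <- attr(rates, "sample_rate") %||% infer_fs(rates$time_s)
  out <- tibble::as_tibble(rates)
  out$afferent_rate_sps <- params$efficacy * out$final_rate_pps
  mod <- params$efficacy * (out$final_rate_pps - params$r0)
  if (asymmetry != 1) mod <- ifelse(mod < 0, asymmetry * mod, mod)
  if (params$hp_cutoff > 0) {
    wc <- 2 * pi * params$hp_cutoff
    for (i in seq_len(params$hp_order)) {
      mod <- ct_filter(mod, zeros = 0, poles = -wc, gain = 1, fs)
    }
  }
  out$afferent_mod_sps <- mod
  for (a in c("sample_rate", "warmup_s", "mapping", "stimulus")) {
    attr(out, a) <- attr(rates, a)
  }
  attr(out, "sample_rate") <- fs
  out
}

# continuous-time zpk of the central chain (TVN * delay-free plant), without
# delay, efficacy, adaptation filter or depression
central_zpk <- function(params) {
  list(zeros = -1 / params$t_c,
       poles = c(-1 / params$t_vor, -1 / params$t_e2),
       gain = -params$gvor / params$t_e2)
}

#' Simulate slow-phase eye velocity from the afferent rate
#'
#' Applies the central VOR chain — vestibular-nucleus velocity storage, the
#' reduced neural-integrator/plant stage `1/(s Te2 + 1)`, the pathway delay
#' `tau` (an integer-sample shift), and the `(1 - depression)` scale — to the
#' high-passed afferent modulation. Compensatory (contralateral) eye movement
#' is negative for positive afferent modulation.
#'
#' @param afferent Output of [pulses_to_afferent_rate()] (needs
#'   `afferent_mod_sps`).
#' @param params A [vor_params()] object.
#' @return The input tibble with an added `eye_vel_dps` column.
#' @export
simulate_eye_velocity <- function(afferent, params) {
  stopifnot(inherits(params, "vp_vor_params"), is.data.frame(afferent),
            "afferent_mod_sps" %in% names(afferent))
  fs <- attr(afferent, "sample_rate") %||% infer_fs(afferent$time_s)
  zpk <- central_zpk(params)
  ev <- ct_filter(afferent$afferent_mod_sps, zpk$zeros, zpk$poles, zpk$gain, fs)
  ev <- delay_shift(ev, round(params$tau * fs))
  out <- tibble::as_tibble(afferent)
  out$eye_vel_dps <- (1 - params$depression) * ev
  for (a in c("sample_rate", "warmup_s", "mapping", "stimulus")) {
    attr(out, a) <- attr(afferent, a)
  }
  attr(out, "sample_rate") <- fs
  out
}

#' Analytic frequency response of the afferent-to-eye chain
#'
#' Exact continuous-domain response of the full pathway from commanded
#' pulse-rate modulation to eye velocity (efficacy, adaptation high-pass,
#' velocity storage, delay, plant, depression). Serves as the oracle for the
#' discrete-time simulation and as ground truth for synthetic recordings.
#'
#' @param params A [vor_params()] object.
#' @param frequencies Positive frequencies (Hz).
#' @param include_hp Include the adaptation high-pass (default `TRUE`).
#' @return A tibble `frequency_hz`, `gain`, `phase_deg` plus a `response`
#'   column holding the complex response.
#' @export
vor_chain_response <- function(params, frequencies, include_hp = TRUE) {
  stopifnot(inherits(params, "vp_vor_params"), all(frequencies > 0))
  s <- 1i * 2 * pi * frequencies
  zpk <- central_zpk(params)
  h <- ct_freq_response(zpk$zeros, zpk$poles, zpk$gain, frequencies)
  h <- h * exp(-s * params$tau) * params$efficacy * (1 - params$depression)
  if (include_hp && params$hp_cutoff > 0) {
    wc <- 2 * pi * params$hp_cutoff
    h <- h * (s / (s + wc))^params$hp_order
  }
  tibble::tibble(frequency_hz = frequencies, gain = Mod(h),
                 phase_deg = Arg(h) * 180 / pi, response = h)
}

#' Peak stimulation rate versus peak evoked eye velocity
#'
#' For each condition (a mapping driven by a stimulus) runs the encoder and
#' the forward model and records the paired maxima: the peak commanded pulse
#' rate and the peak absolute slow-phase eye velocity (both measured after the
#' encoder warm-up). This is the model-side analogue of plotting maximum
#' evoked eye velocity against maximum stimulation rate, and it feeds
#' [estimate_efficacy()].
#'
#' @param conditions A data frame with list-columns `mapping`
#'   ([build_mapping()] objects) and `stimulus` ([stimulus_spec()] objects);
#'   any other columns (labels) are carried through.
#' @param params A [vor_params()] object.
#' @return The input tibble with added columns `frequency_hz`,
#'   `max_rate_pps`, and `max_eye_vel_dps`.
#' @export
peak_velocity_curve <- function(conditions, params) {
  stopifnot(is.data.frame(conditions),
            all(c("mapping", "stimulus") %in% names(conditions)))
  if (nrow(conditions) == 0L) stop("empty condition list", call. = FALSE)
  res <- purrr::pmap(list(conditions$mapping, conditions$stimulus),
    function(mapping, stimulus) {
      enc <- encode_head_velocity(make_stimulus(stimulus), mapping)
      sim <- simulate_eye_velocity(pulses_to_afferent_rate(enc, params), params)
      keep <- sim$time_s >= attr(enc, "warmup_s")
      tibble::tibble(
        frequency_hz = stimulus$frequency %||% NA_real_,
        max_rate_pps = max(sim$final_rate_pps[keep]),
        max_eye_vel_dps = max(abs(sim$eye_vel_dps[keep]))
      )
    })
  dplyr::bind_cols(tibble::as_tibble(conditions), dplyr::bind_rows(res))
}
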