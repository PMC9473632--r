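#' Stimulus specification
#'
#' Describes one head-motion stimulus of the study design: sinusoidal
#' rotations (50 deg/s peak at one of 0.2, 0.5, 1, 2, 5, 10, 20 Hz; 10 cycles
#' per presentation) or brief transients mimicking natural head turns (about
#' 150 ms long, 200 deg/s peak). Any positive frequency/peak is accepted.
#'
#' Transients are embedded in a quiet record: `pre_pad_s` seconds of zero
#' velocity before onset (needed by the latency estimator's baseline window)
#' and `post_pad_s` after the pulse ends.
#'
#' @param type `"sinusoid"` or `"transient"`.
#' @param frequency Sinusoid frequency (Hz).
#' @param peak_velocity Peak angular velocity (deg/s); defaults 50 (sinusoid)
#'   or 200 (transient).
#' @param n_cycles Number of sinusoidal cycles (default 10).
#' @param duration Transient duration (s, default 0.150).
#' @param direction `"on"` (toward the implanted side; positive velocity) or
#'   `"off"`.
#' @param sample_rate Hz (default 1000).
#' @param pre_pad_s,post_pad_s Zero-velocity padding around a transient (s).
#' @return An object of class `vp_stimulus`.
#' @examples
#' stimulus_spec("sinusoid", frequency = 2)
#' stimulus_spec("transient", direction = "off")
#' @export
stimulus_spec <- function(type = c("sinusoid", "transient"), frequency = NULL,
                          peak_velocity = NULL, n_cycles = 10,
                          duration = 0.150, direction = c("on", "off"),
                          sample_rate = 1000, pre_pad_s = 0.3,
                          post_pad_s = 0.5) {
  type <- match.arg(type)
  direction <- match.arg(direction)
  peak_velocity <- peak_velocity %||% switch(type, sinusoid = 50, transient = 200)
  stopifnot(peak_velocity > 0, sample_rate > 0, n_cycles >= 1)
  if (type == "sinusoid") {
    if (is.null(frequency) || frequency <= 0) {
      stop("a positive `frequency` is required for a sinusoid", call. = FALSE)
    }
  } else if (duration <= 0) {
    stop("`duration` must be positive", call. = FALSE)
  }
  structure(
    list(type = type, frequency = frequency, peak_velocity = peak_velocity,
         n_cycles = n_cycles, duration = duration, direction = direction,
         sample_rate = sample_rate, pre_pad_s = pre_pad_s,
         post_pad_s = post_pad_s),
    class = "vp_stimulus"
  )
}

#' Generate a head-velocity stimulus series
#'
#' Sinusoids are `peak * sin(2 pi f t)` for `n_cycles` complete cycles (sign
#' flipped for the "off" direction). Transients are single-peaked raised-
#' cosine velocity pulses, `peak/2 * (1 - cos(2 pi t / duration))`, signed by
#' direction, with the peak at `duration/2` after onset.
#'
#' @param spec A [stimulus_spec()].
#' @return A tibble `time_s`, `head_vel_dps` with attributes `sample_rate`
#'   and `stimulus` (including `onset_s` for transients).
#' @export
make_stimulus <- function(spec) {
  stopifnot(inherits(spec, "vp_stimulus"))
  fs <- spec$sample_rate
  sgn <- if (spec$direction == "on") 1 else -1
  if (spec$type == "sinusoid") {
    n <- round(spec$n_cycles * fs / spec$frequency)
    t <- (seq_len(n) - 1) / fs
    v <- sgn * spec$peak_velocity * sin(2 * pi * spec$frequency * t)
    onset <- 0
  } else {
    n_pre <- round(spec$pre_pad_s * fs)
    n_pulse <- round(spec$duration * fs)
    n_post <- round(spec$post_pad_s * fs)
    t <- (seq_len(n_pre + n_pulse + n_post) - 1) / fs
    v <- numeric(length(t))
    tp <- (seq_len(n_pulse) - 1) / fs
    v[n_pre + seq_len(n_pulse)] <-
      sgn * spec$peak_velocity / 2 * (1 - cos(2 * pi * tp / spec$duration))
    onset <- n_pre / fs
  }
  out <- tibble::tibble(time_s = t, head_vel_dps = v)
  spec$onset_s <- onset
  attr(out, "sample_rate") <- fs
  attr(out, "stimulus") <- spec
  out
}

#' Cycles to record so the analysis minima survive warm-up and saccades
#'
#' The study protocol delivers sinusoids in 10-cycle presentations, with as
#' many presentations as needed. This helper returns a whole number of
#' presentations (a multiple of 10 cycles) large enough that, after dropping
#' the encoder warm-up cycles and allowing `margin` headroom for cycles lost
#' to saccade masking, the per-frequency minimum included-cycle counts
#' (3 at 0.2-0.5 Hz, 10 above) are still met.
#'
#' @param frequency Stimulus frequency (Hz).
#' @param mapping The [build_mapping()] in use (its warm-up depends on the
#'   mapping's time constants).
#' @param margin Multiplier on the minimum cycle count (default 1.5).
#' @return An integer number of cycles (multiple of 10, at least 10).
#' @export
n_cycles_for <- function(frequency, mapping, margin = 1.5) {
  need <- ceiling(margin * cycle_rules(frequency)$min_cycles) +
    ceiling(mapping_warmup(mapping) * frequency)
  max(10L, 10L * ceiling(need / 10))
}

#' Measurement/behavioural nuisance model for synthetic recordings
#'
#' Describes the non-vestibular content injected into synthetic eye-position
#' traces: white Gaussian position noise (emulating coil measurement noise)
#' and stereotyped saccades at Poisson-distributed times. The defaults are
#' plausible for a head-fixed monkey in darkness, not estimates fitted to any
#' recording: 0.02 deg measurement noise, 0.5 saccades/s, 3 deg amplitude.
#'
#' @param position_noise_sd Eye-position noise SD (deg).
#' @param saccade_rate Mean saccade rate (events/s).
#' @param saccade_amplitude Saccade amplitude (deg); signs are random.
#' @param seed Integer seed used by [synthesize_recording()].
#' @return An object of class `vp_noise`.
#' @export
noise_spec <- function(position_noise_sd = 0.02, saccade_rate = 0.5,
                       saccade_amplitude = 3, seed = 1L) {
  stopifnot(position_noise_sd >= 0, saccade_rate >= 0, saccade_amplitude >= 0)
  structure(list(position_noise_sd = position_noise_sd,
                 saccade_rate = saccade_rate,
                 saccade_amplitude = saccade_amplitude,
                 seed = as.integer(seed)),
            class = "vp_noise")
}

# minimum-jerk position step of given amplitude/duration, as increments
minimum_jerk_step <- function(amplitude, n_samples) {
  tau <- seq_len(n_samples) / n_samples
  amplitude * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

#' Synthesize a 1 kHz eye-movement recording with ground truth
#'
#' Runs the deterministic forward model (encoder, afferent stage, central VOR
#' chain), applies a static on/off asymmetry, integrates eye velocity to eye
#' position, and adds the nuisance content: white Gaussian position noise and
#' minimum-jerk saccades (30 ms) at Poisson times. The unilateral-stimulation
#' asymmetry is modeled by scaling ipsilaterally directed ("off"-response)
#' model eye velocity — samples with positive eye velocity — by `asymmetry`.
#'
#' The `truth` attribute stores everything the analysis pipeline is later
#' asked to recover, without re-running the model: for sinusoids the gain and
#' phase of the noiseless eye-velocity fundamental relative to head velocity
#' (projection over post-warm-up complete cycles; phase 0 = perfectly
#' compensatory, lead positive), for transients the programmed pathway
#' latency and the peak-velocity gain; plus the saccade intervals and all
#' generator parameters.
#'
#' @param stimulus A [stimulus_spec()].
#' @param mapping A [build_mapping()].
#' @param params A [vor_params()].
#' @param noise A [noise_spec()].
#' @param asymmetry Scale on ipsilaterally directed eye velocity (default 0.8;
#'   1 = symmetric).
#' @param seed Overrides `noise$seed`.
#' @return A tibble `time_s`, `head_vel_dps`, `pulse_rate_pps`, `eye_pos_deg`
#'   with attributes `truth`, `sample_rate`, `warmup_s`, `stimulus`.
#' @examples
#' rec <- synthesize_recording(stimulus_spec("sinusoid", frequency = 2),
#'                             build_mapping("regular"),
#'                             vor_params("monkey_Y_like"))
#' attr(rec, "truth")$gain
#' @export
synthesize_recording <- function(stimulus, mapping, params,
                                 noise = noise_spec(), asymmetry = 0.8,
                                 seed = noise$seed) {
  stopifnot(inherits(stimulus, "vp_stimulus"), inherits(mapping, "vp_mapping"),
            inherits(params, "vp_vor_params"), inherits(noise, "vp_noise"))
  head <- make_stimulus(stimulus)
  fs <- attr(head, "sample_rate")
  enc <- encode_head_velocity(head, mapping)
  aff <- pulses_to_afferent_rate(enc, params)
  sim <- simulate_eye_velocity(aff, params)
  ev <- sim$eye_vel_dps
  if (asymmetry != 1) ev <- ifelse(ev > 0, asymmetry * ev, ev)
  warmup <- attr(enc, "warmup_s")
  stim <- attr(head, "stimulus")

  truth <- list(params = params, mapping = mapping, stimulus = stim,
                asymmetry = asymmetry, seed = seed, warmup_s = warmup)
  n <- nrow(head)
  if (stimulus$type == "sinusoid") {
    f <- stimulus$frequency
    first_cycle <- ceiling(warmup * f)
    use <- head$time_s >= first_cycle / f
    ch <- fundamental_complex(head$head_vel_dps, head$time_s, f, use)
    ce <- fundamental_complex(ev, head$time_s, f, use)
    ratio <- -ce / ch   # compensatory convention: eye = -gain * head
    truth$gain <- Mod(ratio)
    truth$phase_deg <- Arg(ratio) * 180 / pi
  } else {
    truth$latency_ms <- params$tau * 1000
    truth$gain <- max(abs(ev)) / stimulus$peak_velocity
    i_head <- which.max(abs(head$head_vel_dps))
    i_eye <- which.max(abs(ev))
    truth$peak_time_diff_ms <- (head$time_s[i_eye] - head$time_s[i_head]) * 1000
    truth$onset_s <- stim$onset_s
  }

  # trapezoidal integration: zero phase error at all frequencies
  pos <- cumsum(c(0, (ev[-1] + ev[-n]) / 2)) / fs
  saccades <- tibble::tibble(start_s = numeric(), end_s = numeric())
  with_local_seed(seed, {
    if (noise$saccade_rate > 0) {
      duration_s <- n / fs
      k <- stats::rpois(1, noise$saccade_rate * duration_s)
      if (k > 0) {
        starts <- sort(stats::runif(k, 0, duration_s - 0.030))
        n_sac <- 30L * round(fs / 1000)
        for (s0 in starts) {
          i0 <- round(s0 * fs) + 1L
          idx <- i0:min(i0 + n_sac - 1L, n)
          step <- minimum_jerk_step(sample(c(-1, 1), 1) * noise$saccade_amplitude,
                                    length(idx))
          pos[idx] <- pos[idx] + step
          if (max(idx) < n) pos[(max(idx) + 1L):n] <-
              pos[(max(idx) + 1L):n] + step[length(step)]
        }
        saccades <- tibble::tibble(start_s = (round(starts * fs)) / fs,
                                   end_s = (round(starts * fs) + n_sac) / fs)
      }
    }
    if (noise$position_noise_sd > 0) {
      pos <- pos + stats::rnorm(n, 0, noise$position_noise_sd)
    }
  })
  truth$saccades <- saccades

  out <- tibble::tibble(time_s = head$time_s,
                        head_vel_dps = head$head_vel_dps,
                        pulse_rate_pps = enc$final_rate_pps,
                        eye_pos_deg = pos)
  attr(out, "sample_rate") <- fs
  attr(out, "warmup_s") <- warmup
  attr(out, "stimulus") <- stim
  attr(out, "truth") <- truth
  out
}
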