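#' Preprocess an eye-position recording into slow-phase eye velocity
#'
#' The standard preprocessing chain for 1 kHz eye-coil data: zero-phase 51-tap
#' Hamming-window low-pass at 125 Hz on position, central-difference
#' differentiation to velocity, saccade detection and masking, then a
#' zero-phase 51-tap Hamming low-pass at 50 Hz on the slow-phase velocity.
#'
#' Saccades are detected where the velocity deviates from a slow-phase
#' reference — the velocity low-passed at `reference_cutoff` Hz with a sharp
#' (201-tap) zero-phase FIR — by more than `saccade_threshold` deg/s. The
#' reference cutoff sits above the stimulus band (up to 20 Hz) but below the
#' frequency content of a 30 ms saccade, so slow-phase modulation cancels in
#' the deviation while saccades do not. Detected intervals are padded by
#' `pad_ms` on both sides and merged. Masked samples are flagged
#' (`slow_phase = FALSE`), never interpolated in the output; the final
#' smoothing filter runs on a gap-bridged copy only so that saccade energy
#' does not leak into neighbouring slow-phase samples.
#'
#' @param recording A data frame with `time_s` and `eye_pos_deg` (1 kHz);
#'   other columns (e.g. `head_vel_dps`) are carried through.
#' @param saccade_threshold Velocity-deviation threshold (deg/s).
#' @param reference_cutoff Cutoff (Hz) of the slow-phase reference filter
#'   used for detection; it is separate from the 50 Hz output filter.
#' @param pad_ms Padding added around each detected saccade (ms).
#' @return A tibble `time_s`, `eye_vel_dps`, `slow_phase` (plus carried
#'   columns), with attributes `saccades` (tibble of `start_s`, `end_s`),
#'   `sample_rate`, and any `warmup_s`/`stimulus`/`truth` attributes of the
#'   input.
#' @export
preprocess_eye <- function(recording, saccade_threshold = 50,
                           reference_cutoff = 10, pad_ms = 10) {
  stopifnot(is.data.frame(recording),
            all(c("time_s", "eye_pos_deg") %in% names(recording)))
  fs <- attr(recording, "sample_rate") %||% infer_fs(recording$time_s)
  n <- nrow(recording)
  pos <- fir_lowpass(recording$eye_pos_deg, fs, 125)
  vel <- c(pos[2] - pos[1],
           (pos[-(1:2)] - pos[seq_len(n - 2)]) / 2,
           pos[n] - pos[n - 1]) * fs

  ref_taps <- min(201L, 2L * floor((n - 2L) / 6L) + 1L)
  reference <- fir_lowpass(vel, fs, reference_cutoff, taps = ref_taps)
  mask <- abs(vel - reference) > saccade_threshold
  pad <- round(pad_ms / 1000 * fs)
  if (any(mask) && pad > 0) {
    idx <- which(mask)
    for (d in seq_len(pad)) {
      mask[pmax(idx - d, 1L)] <- TRUE
      mask[pmin(idx + d, n)] <- TRUE
    }
  }

  # bridge masked gaps for filtering only; flagged samples stay flagged
  vel_bridge <- vel
  if (any(mask)) {
    ok <- which(!mask)
    if (length(ok) < 2L) stop("no slow-phase samples detected", call. = FALSE)
    vel_bridge <- stats::approx(recording$time_s[ok], vel[ok],
                                xout = recording$time_s, rule = 2)$y
  }
  vel_out <- fir_lowpass(vel_bridge, fs, 50)

  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sacc <- tibble::tibble(start_s = recording$time_s[starts[r$values]],
                         end_s = recording$time_s[ends[r$values]])

  out <- tibble::as_tibble(recording)
  out$eye_pos_deg <- NULL
  out$eye_vel_dps <- vel_out
  out$slow_phase <- !mask
  attr(out, "sample_rate") <- fs
  attr(out, "saccades") <- sacc
  for (a in c("warmup_s", "stimulus", "truth")) {
    attr(out, a) <- attr(recording, a)
  }
  out
}

# per-frequency slow-phase inclusion threshold and minimum cycle count
cycle_rules <- function(frequency) {
  if (frequency <= 0.5) {
    list(min_fraction = 0.40, min_cycles = 3L)
  } else {
    list(min_fraction = 0.60, min_cycles = 10L)
  }
}

#' Per-cycle sinusoidal fits of slow-phase eye velocity
#'
#' For every complete stimulus cycle, fits
#' `a sin(2 pi f t) + b cos(2 pi f t) + c` by least squares over the unmasked
#' (slow-phase) samples and converts the coefficients to a VOR gain and phase.
#' The eye-velocity sign is inverted relative to head velocity, so phase 0
#' means perfectly compensatory and positive phase means the eye leads.
#' Cycles are included when their slow-phase fraction is at least 40%
#' (frequencies up to 0.5 Hz) or 60% (higher frequencies).
#'
#' @param velocity Output of [preprocess_eye()] (columns `time_s`,
#'   `eye_vel_dps`, `slow_phase`).
#' @param stimulus The [stimulus_spec()] of the recording (defaults to the
#'   `stimulus` attribute).
#' @param skip_s Drop cycles that start before this time (defaults to the
#'   recording's encoder `warmup_s` attribute, so startup transients of the
#'   forward model are not scored as steady state).
#' @param compensate_filters Correct the fitted amplitude for the known
#'   amplitude response of the preprocessing chain (the two zero-phase FIR
#'   low-passes and the central-difference derivative) at the stimulus
#'   frequency (default `TRUE`). The chain is zero phase, so phases need no
#'   correction. The correction is about 0.1% at 1 Hz and about 3% at 20 Hz.
#' @return A tibble with one row per analysed cycle: `cycle`, `frequency_hz`,
#'   `gain`, `phase_deg`, `offset_dps`, `slow_phase_fraction`, `included`.
#' @export
fit_cycles <- function(velocity, stimulus = attr(velocity, "stimulus"),
                       skip_s = attr(velocity, "warmup_s") %||% 0,
                       compensate_filters = TRUE) {
  stopifnot(is.data.frame(velocity),
            all(c("time_s", "eye_vel_dps", "slow_phase") %in% names(velocity)))
  if (is.null(stimulus) || !inherits(stimulus, "vp_stimulus") ||
      stimulus$type != "sinusoid") {
    stop("`stimulus` must be a sinusoid stimulus_spec", call. = FALSE)
  }
  f <- stimulus$frequency
  fs <- attr(velocity, "sample_rate") %||% infer_fs(velocity$time_s)
  rules <- cycle_rules(f)
  sgn <- if (stimulus$direction == "on") 1 else -1
  t_end <- velocity$time_s[nrow(velocity)]
  first <- ceiling(skip_s * f)
  cycles <- seq(first, floor((t_end + 1 / fs) * f) - 1)
  if (length(cycles) == 0L) stop("no complete cycles to fit", call. = FALSE)
  amp_corr <- if (isTRUE(compensate_filters)) preproc_chain_gain(f, fs) else 1
  purrr::map_dfr(cycles, function(j) {
    in_cycle <- velocity$time_s >= j / f & velocity$time_s < (j + 1) / f
    sp <- velocity$slow_phase & in_cycle
    frac <- sum(sp) / sum(in_cycle)
    if (sum(sp) >= 8L) {
      cf <- fit_sincos(velocity$eye_vel_dps, velocity$time_s, f, sp)
      amp <- sqrt(cf[["a"]]^2 + cf[["b"]]^2) / amp_corr
      gain <- amp / stimulus$peak_velocity
      phase <- atan2(-sgn * cf[["b"]], -sgn * cf[["a"]]) * 180 / pi
      offset <- cf[["offset"]]
    } else {
      gain <- NA_real_; phase <- NA_real_; offset <- NA_real_
    }
    tibble::tibble(cycle = j, frequency_hz = f, gain = gain,
                   phase_deg = phase, offset_dps = offset,
                   slow_phase_fraction = frac,
                   included = is.finite(gain) && frac >= rules$min_fraction)
  })
}

#' Summarize cycle fits into a frequency-response table
#'
#' Aggregates per-cycle gains and phases across frequencies into mean and
#' standard-error summaries, enforcing the minimum included-cycle counts
#' (3 cycles at 0.2-0.5 Hz, 10 at higher frequencies). Also computes the
#' derived scalars used to characterize a mapping: the log-linear slope of
#' gain over 5-20 Hz (linear regression of mean gain on log10 frequency) and
#' the mean absolute phase over 5-20 Hz. When a second set of cycle fits from
#' the doubled-gain condition is supplied, the per-frequency gain ratio
#' (each x2 data point divided by the mean x1 gain, then averaged) is added;
#' when a normalization reference is supplied, normalized gains are added.
#'
#' @param fits Cycle-fit tibble from [fit_cycles()], possibly row-bound
#'   across frequencies.
#' @param fits_x2 Optional cycle fits of the matching x2-gain condition.
#' @param normalize_by Optional reference table with columns `frequency_hz`
#'   and `mean_gain`; adds `norm_gain = mean_gain / reference`.
#' @param hf_range Frequency range (Hz) for the slope and mean-|phase|
#'   scalars.
#' @return A `vp_freq_response` tibble (per frequency: `mean_gain`,
#'   `se_gain`, `mean_phase_deg`, `se_phase_deg`, `n_cycles`, and optionally
#'   `gain_ratio`, `norm_gain`). The derived scalars are stored as attributes
#'   and surfaced by [glance.vp_freq_response()].
#' @export
summarize_response <- function(fits, fits_x2 = NULL, normalize_by = NULL,
                               hf_range = c(5, 20)) {
  stopifnot(is.data.frame(fits), "frequency_hz" %in% names(fits))
  inc <- dplyr::filter(fits, .data$included)
  tab <- inc |>
    dplyr::group_by(.data$frequency_hz) |>
    dplyr::summarise(
      mean_gain = mean(.data$gain),
      se_gain = stats::sd(.data$gain) / sqrt(dplyr::n()),
      mean_phase_deg = mean(.data$phase_deg),
      se_phase_deg = stats::sd(.data$phase_deg) / sqrt(dplyr::n()),
      n_cycles = dplyr::n(), .groups = "drop"
    )
  need <- vapply(tab$frequency_hz, function(f) cycle_rules(f)$min_cycles, 1L)
  short <- tab$n_cycles < need
  if (any(short)) {
    stop("insufficient cycles: ",
         paste0(tab$frequency_hz[short], " Hz has ", tab$n_cycles[short],
                " (needs ", need[short], ")", collapse = "; "),
         call. = FALSE)
  }
  hf <- dplyr::filter(tab, .data$frequency_hz >= hf_range[1],
                      .data$frequency_hz <= hf_range[2])
  if (nrow(hf) >= 2L) {
    slope <- unname(stats::coef(
      stats::lm(mean_gain ~ log10(frequency_hz), data = hf))[2])
  } else {
    slope <- NA_real_
  }
  mean_abs_phase <- if (nrow(hf) >= 1L) mean(abs(hf$mean_phase_deg)) else NA_real_
  if (!is.null(fits_x2)) {
    inc2 <- dplyr::filter(fits_x2, .data$included)
    ratio <- inc2 |>
      dplyr::inner_join(dplyr::select(tab, "frequency_hz", "mean_gain"),
                        by = "frequency_hz") |>
      dplyr::group_by(.data$frequency_hz) |>
      dplyr::summarise(gain_ratio = mean(.data$gain / .data$mean_gain),
                       .groups = "drop")
    tab <- dplyr::left_join(tab, ratio, by = "frequency_hz")
  }
  if (!is.null(normalize_by)) {
    stopifnot(all(c("frequency_hz", "mean_gain") %in% names(normalize_by)))
    ref <- dplyr::select(normalize_by, "frequency_hz", ref_gain = "mean_gain")
    tab <- dplyr::left_join(tab, ref, by = "frequency_hz") |>
      dplyr::mutate(norm_gain = .data$mean_gain / .data$ref_gain) |>
      dplyr::select(-"ref_gain")
  }
  structure(tab, class = c("vp_freq_response", class(tab)),
            log_gain_slope = slope, mean_abs_phase_hf = mean_abs_phase,
            hf_range = hf_range)
}

#' @describeIn summarize_response One-row tibble of the derived scalars
#'   (`log_gain_slope`, `mean_abs_phase_hf`, `n_frequencies`).
#' @param x A `vp_freq_response` table.
#' @param ... Unused.
#' @export
glance.vp_freq_response <- function(x, ...) {
  tibble::tibble(
    log_gain_slope = attr(x, "log_gain_slope"),
    mean_abs_phase_hf = attr(x, "mean_abs_phase_hf"),
    n_frequencies = nrow(x)
  )
}

#' Bootstrap standard error of the mean phase
#'
#' Nonparametric bootstrap over cycle fits (the independent resampling unit):
#' cycles are resampled with replacement `n_iterations` times (2,000 by
#' default) and the standard deviation of the resampled statistic is
#' returned. The statistic is the mean phase of the included cycles, or the
#' difference in mean phase between two conditions when `fits2` is supplied.
#'
#' @param fits Cycle-fit tibble (included cycles are used).
#' @param n_iterations Bootstrap iterations.
#' @param seed Integer seed for reproducibility.
#' @param fits2 Optional second condition; the statistic becomes
#'   `mean(phase2) - mean(phase1)`.
#' @return The bootstrap standard error (degrees).
#' @export
bootstrap_phase_se <- function(fits, n_iterations = 2000, seed = 1L,
                               fits2 = NULL) {
  ph1 <- dplyr::filter(fits, .data$included)$phase_deg
  if (length(ph1) == 0L) stop("no included cycles to resample", call. = FALSE)
  ph2 <- if (!is.null(fits2)) dplyr::filter(fits2, .data$included)$phase_deg
  with_local_seed(seed, {
    reps <- vapply(seq_len(n_iterations), function(i) {
      m1 <- mean(sample(ph1, replace = TRUE))
      if (is.null(ph2)) m1 else mean(sample(ph2, replace = TRUE)) - m1
    }, numeric(1))
    stats::sd(reps)
  })
}

#' Transient-response metrics: latency, gain, peak timing
#'
#' Quantifies the averaged slow-phase response to a transient head movement.
#' Trials containing any saccade within 50 ms of the stimulus window are
#' excluded; at least 4 eligible trials are required. On the trial-averaged
#' trace, the response onset latency is the x-axis intercept of a line fitted
#' to the 10 samples before and after the first crossing of the 2 SD
#' threshold (SD of the 100 ms baseline preceding stimulus onset). Two
#' numerical guards make the rule total: for noise-free traces with zero
#' baseline SD a floor of 1% of the peak response stands in for the
#' threshold, and the crossing must stay above threshold for `n_fit`
#' consecutive samples so isolated noise excursions are not scored as onset. Gain is the maximum absolute eye velocity
#' divided by the peak head velocity, and the peak-timing difference is the
#' time of the eye-velocity extremum minus the time of the head-velocity
#' peak (negative = eye peak leads).
#'
#' @param trials List of preprocessed trials ([preprocess_eye()] outputs with
#'   a `head_vel_dps` column and `saccades` attribute), aligned to the same
#'   stimulus.
#' @param stimulus The transient [stimulus_spec()] (defaults to the first
#'   trial's attribute).
#' @param exclusion_pad_s Saccade-free margin around the stimulus (s).
#' @param baseline_s Baseline-window length before onset for the SD (s).
#' @param n_fit Samples on each side of the threshold crossing used in the
#'   latency line fit.
#' @return A one-row tibble: `gain`, `peak_time_diff_ms`, `latency_ms`,
#'   `n_trials`.
#' @export
transient_metrics <- function(trials, stimulus = attr(trials[[1]], "stimulus"),
                              exclusion_pad_s = 0.05, baseline_s = 0.10,
                              n_fit = 10L) {
  stopifnot(is.list(trials), length(trials) >= 1L,
            inherits(stimulus, "vp_stimulus"), stimulus$type == "transient")
  onset <- stimulus$onset_s %||% stimulus$pre_pad_s
  win <- c(onset - exclusion_pad_s,
           onset + stimulus$duration + exclusion_pad_s)
  eligible <- purrr::keep(trials, function(tr) {
    sc <- attr(tr, "saccades")
    is.null(sc) || nrow(sc) == 0L ||
      !any(sc$end_s >= win[1] & sc$start_s <= win[2])
  })
  if (length(eligible) < 4L) {
    stop("insufficient trials: ", length(eligible),
         " saccade-free trials (need >= 4)", call. = FALSE)
  }
  t <- eligible[[1]]$time_s
  fs <- attr(eligible[[1]], "sample_rate") %||% infer_fs(t)
  ev <- rowMeans(vapply(eligible, function(tr) tr$eye_vel_dps,
                        numeric(length(t))))
  head_v <- eligible[[1]]$head_vel_dps

  base <- t >= onset - baseline_s & t < onset
  b_mean <- mean(ev[base])
  b_sd <- stats::sd(ev[base])
  resp <- t >= onset
  peak <- max(abs(ev[resp] - b_mean))
  thr <- max(2 * b_sd, 0.01 * peak)
  dev <- abs(ev - b_mean)
  # first crossing that stays above threshold for n_fit samples, so isolated
  # noise excursions past the 2 SD line are not scored as the response onset
  run <- as.numeric(stats::filter(as.numeric(dev > thr), rep(1, n_fit),
                                  sides = 1))
  sustained <- which(resp & !is.na(run) & run == n_fit)
  if (length(sustained) == 0L) stop("no threshold crossing found", call. = FALSE)
  cross <- sustained[1] - n_fit + 1L
  idx <- max(1L, cross - n_fit):min(length(t), cross + n_fit - 1L)
  fit <- stats::lm(y ~ x, data = data.frame(x = t[idx], y = dev[idx]))
  x0 <- -stats::coef(fit)[[1]] / stats::coef(fit)[[2]]
  latency_ms <- (x0 - onset) * 1000

  i_eye <- which.max(dev * resp)
  i_head <- which.max(abs(head_v))
  tibble::tibble(
    gain = peak / max(abs(head_v)),
    peak_time_diff_ms = (t[i_eye] - t[i_head]) * 1000,
    latency_ms = latency_ms,
    n_trials = length(eligible)
  )
}

#' Subtract a baseline condition from a stimulation condition
#'
#' Pointwise difference of two trial-averaged velocity traces aligned to
#' stimulus onset. Used for physical-motion conditions, where the
#' prosthesis-evoked component is the difference between the mapped
#' stimulation condition and the baseline-only condition.
#'
#' @param condition,baseline Data frames with `time_s` and `eye_vel_dps`,
#'   equal length and alignment.
#' @return `condition` with `eye_vel_dps` replaced by the difference.
#' @export
subtract_baseline <- function(condition, baseline) {
  stopifnot(is.data.frame(condition), is.data.frame(baseline),
            "eye_vel_dps" %in% names(condition),
            "eye_vel_dps" %in% names(baseline))
  if (nrow(condition) != nrow(baseline)) {
    stop("condition and baseline traces differ in length (",
         nrow(condition), " vs ", nrow(baseline), ")", call. = FALSE)
  }
  out <- tibble::as_tibble(condition)
  out$eye_vel_dps <- condition$eye_vel_dps - baseline$eye_vel_dps
  out
}
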