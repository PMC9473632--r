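#' Sigmoidal rate-limiting nonlinearity
#'
#' The prosthesis caps its commanded pulse rate with a fixed sigmoid so that
#' the delivered rate stays inside the afferent operating range. The shape is
#' pinned down by three conventions: the upper bound is `c3` (default 500 pps),
#' the steepness is `c1 = 4/c3` so the maximum slope (at the inflection point
#' `c2`) is exactly 1, and `c2` is placed so the baseline rate `r0` (default
#' 150 pps) is a fixed point of the nonlinearity.
#'
#' @param c3 Upper bound of the output rate (pps).
#' @param r0 Baseline pulse rate (pps); must satisfy `0 < r0 < c3`.
#' @return An object of class `vp_sigmoid` with fields `c1`, `c2`, `c3`, `r0`.
#' @examples
#' sg <- sigmoid_spec()
#' apply_sigmoid(150, sg)   # baseline is a fixed point
#' apply_sigmoid(1e6, sg)   # saturates at 500
#' @export
sigmoid_spec <- function(c3 = 500, r0 = 150) {
  stopifnot(is.numeric(c3), c3 > 0, is.numeric(r0), r0 > 0, r0 < c3)
  c1 <- 4 / c3
  c2 <- r0 + log(c3 / r0 - 1) / c1
  structure(list(c1 = c1, c2 = c2, c3 = c3, r0 = r0), class = "vp_sigmoid")
}

#' Apply the rate-limiting sigmoid
#'
#' Maps an unbounded linear-stage pulse rate into `(0, c3)`. Negative linear
#' rates are legal inputs: the sigmoid, not a hard clip, enforces positivity.
#'
#' @param linear_rate Numeric vector of pre-sigmoid rates (pps).
#' @param spec A [sigmoid_spec()].
#' @return Numeric vector of bounded rates (pps), strictly inside `(0, c3)`.
#' @export
apply_sigmoid <- function(linear_rate, spec = sigmoid_spec()) {
  stopifnot(inherits(spec, "vp_sigmoid"), all(is.finite(linear_rate)))
  spec$c3 / (1 + exp(-spec$c1 * (linear_rate - spec$c2)))
}

# printed constants of the five head-velocity -> pulse-rate mappings
mapping_registry <- function() {
  list(
    regular         = list(k = 5.056,  T1 = 0.0175, T2 = 0.0027, Tc = 5.7),
    irregular       = list(k = 38.889, T1 = 0.03,   T2 = 0.0006, Tc = 5.7),
    super_high_pass = list(k = 76.76,  T1 = 0.06,   T2 = 0.0006, Tc = 5.7),
    mixed           = list(n = 1.5923),
    static          = list(flat_gain = 0.78)
  )
}

#' Build a head-velocity-to-pulse-rate mapping
#'
#' Constructs one of the five encoder mappings that convert angular head
#' velocity (deg/s) into a commanded stimulation pulse rate (pps). The
#' `regular` and `irregular` mappings reproduce the high-pass tuning of the
#' two semicircular-canal afferent classes via the transfer function
#' `H(s) = k s (s + 1/T1) / ((s + 1/Tc)(s + 1/T2))`; `super_high_pass` is an
#' exaggerated variant; `mixed` averages the regular and irregular responses
#' and rescales by a constant `n`; `static` is the conventional flat mapping
#' (0.78 pps per deg/s, no dynamics). Each mapping runs in cascade with the
#' [sigmoid_spec()] nonlinearity around a 150 pps baseline.
#'
#' The doubled-gain condition (`gain_multiplier = 2`) doubles only the overall
#' gain constant (`k`, `n`, or the flat gain); all dynamics are unchanged.
#'
#' The printed mix constant `n = 1.5923` does not actually equalize the mixed
#' mapping's 0.5 Hz gain with the static mapping's 0.78 pps/dps (the regular
#' and irregular responses each already have magnitude 0.78 there, so the
#' printed `n` yields about 1.24). `renormalize_mixed = TRUE` instead solves
#' `n` so that `|H_mixed(0.5 Hz)| = 0.78`, which realizes the stated gain
#' match; both variants are supported and neither is asserted as ground truth.
#'
#' @param kind One of `"regular"`, `"irregular"`, `"mixed"`,
#'   `"super_high_pass"`, `"static"`.
#' @param gain_multiplier 1 or 2.
#' @param renormalize_mixed Logical; see Details. Only affects `kind = "mixed"`.
#' @param r0 Baseline pulse rate (pps).
#' @param sigmoid A [sigmoid_spec()]; defaults to the standard 500 pps bound.
#' @return An object of class `vp_mapping`.
#' @examples
#' build_mapping("regular")
#' build_mapping("static", gain_multiplier = 2)$flat_gain  # 1.56
#' @export
build_mapping <- function(kind, gain_multiplier = 1, renormalize_mixed = FALSE,
                          r0 = 150, sigmoid = sigmoid_spec(r0 = r0)) {
  reg <- mapping_registry()
  if (!is.character(kind) || length(kind) != 1L || !kind %in% names(reg)) {
    stop("unknown mapping kind ", if (is.character(kind)) paste0("'", kind, "'"),
         "; valid kinds: ", paste(names(reg), collapse = ", "), call. = FALSE)
  }
  if (!gain_multiplier %in% c(1, 2)) {
    stop("`gain_multiplier` must be 1 or 2", call. = FALSE)
  }
  m <- c(reg[[kind]],
         list(kind = kind, gain_multiplier = gain_multiplier, r0 = r0,
              sigmoid = sigmoid))
  if (kind == "mixed") {
    m$components <- list(regular = reg$regular, irregular = reg$irregular)
    m$renormalize <- isTRUE(renormalize_mixed)
    if (m$renormalize) {
      hr <- ct_freq_response(c(0, -1 / reg$regular$T1),
                             c(-1 / reg$regular$Tc, -1 / reg$regular$T2),
                             reg$regular$k, 0.5)
      hi <- ct_freq_response(c(0, -1 / reg$irregular$T1),
                             c(-1 / reg$irregular$Tc, -1 / reg$irregular$T2),
                             reg$irregular$k, 0.5)
      m$n <- 0.78 / Mod((hr + hi) / 2)
    }
    m$n <- m$n * gain_multiplier
  } else if (kind == "static") {
    m$flat_gain <- m$flat_gain * gain_multiplier
  } else {
    m$k <- m$k * gain_multiplier
  }
  structure(m, class = "vp_mapping")
}

#' @export
print.vp_mapping <- function(x, ...) {
  cat("<vp_mapping> ", x$kind, " (x", x$gain_multiplier, ")\n", sep = "")
  if (x$kind == "static") {
    cat("  flat gain:", x$flat_gain, "pps per deg/s\n")
  } else if (x$kind == "mixed") {
    cat("  n:", signif(x$n, 6),
        if (isTRUE(x$renormalize)) "(renormalized to 0.78 pps/dps at 0.5 Hz)",
        "\n")
  } else {
    cat("  k:", x$k, "pps per deg/s; T1:", x$T1, "s; T2:", x$T2,
        "s; Tc:", x$Tc, "s\n")
  }
  cat("  baseline:", x$r0, "pps; sigmoid bound:", x$sigmoid$c3, "pps\n")
  invisible(x)
}

# complex linear-stage response H(f) of a mapping (pps per deg/s)
mapping_tf <- function(mapping, f) {
  switch(mapping$kind,
    static = rep(complex(real = mapping$flat_gain), length(f)),
    mixed = {
      cr <- mapping$components$regular
      ci <- mapping$components$irregular
      hr <- ct_freq_response(c(0, -1 / cr$T1), c(-1 / cr$Tc, -1 / cr$T2), cr$k, f)
      hi <- ct_freq_response(c(0, -1 / ci$T1), c(-1 / ci$Tc, -1 / ci$T2), ci$k, f)
      mapping$n * (hr + hi) / 2
    },
    ct_freq_response(c(0, -1 / mapping$T1),
                     c(-1 / mapping$Tc, -1 / mapping$T2), mapping$k, f)
  )
}

#' Analytic frequency response of a mapping's linear stage
#'
#' Evaluates the linear transfer function of a mapping at the requested
#' frequencies. This is the exact continuous-domain response; it serves as the
#' oracle against which the discrete-time filtering in
#' [encode_head_velocity()] is validated.
#'
#' @param mapping A [build_mapping()] object.
#' @param frequencies Positive frequencies (Hz).
#' @return A tibble with columns `frequency_hz`, `gain_pps_per_dps`,
#'   `phase_deg` (phase lead positive; the static mapping has zero phase).
#' @examples
#' mapping_frequency_response(build_mapping("regular"), c(0.5, 2, 20))
#' @export
mapping_frequency_response <- function(mapping, frequencies) {
  stopifnot(inherits(mapping, "vp_mapping"))
  if (!is.numeric(frequencies) || any(!is.finite(frequencies)) ||
      any(frequencies <= 0)) {
    stop("`frequencies` must be positive and finite", call. = FALSE)
  }
  h <- mapping_tf(mapping, frequencies)
  tibble::tibble(
    frequency_hz = frequencies,
    gain_pps_per_dps = Mod(h),
    phase_deg = Arg(h) * 180 / pi
  )
}

# seconds of encoder output to flag as filter warm-up
mapping_warmup <- function(mapping) {
  t1 <- switch(mapping$kind,
    static = return(0),
    mixed = max(mapping$components$regular$T1, mapping$components$irregular$T1),
    mapping$T1
  )
  max(5 * t1, 3 / (2 * pi * 0.2))
}

# linear-stage modulation (pps about baseline) by discrete-time filtering
mapping_filter <- function(mapping, v, fs) {
  switch(mapping$kind,
    static = mapping$flat_gain * v,
    mixed = {
      cr <- mapping$components$regular
      ci <- mapping$components$irregular
      yr <- ct_filter(v, c(0, -1 / cr$T1), c(-1 / cr$Tc, -1 / cr$T2), cr$k, fs)
      yi <- ct_filter(v, c(0, -1 / ci$T1), c(-1 / ci$Tc, -1 / ci$T2), ci$k, fs)
      mapping$n * (yr + yi) / 2
    },
    ct_filter(v, c(0, -1 / mapping$T1),
              c(-1 / mapping$Tc, -1 / mapping$T2), mapping$k, fs)
  )
}

#' Encode head velocity into commanded pulse rates
#'
#' Runs the full linear-nonlinear cascade: the mapping's transfer function is
#' realized as a discrete-time filter (bilinear transform at the series sample
#' rate), the baseline rate `r0` is added, and the result is passed through the
#' rate-limiting sigmoid. The continuous transfer functions are causal and the
#' filter starts from rest, so the first `warmup_s` seconds (stored as an
#' attribute) carry a startup transient and are excluded from steady-state
#' comparisons.
#'
#' @param head A data frame with columns `time_s` (uniform grid) and
#'   `head_vel_dps` (angular head velocity, deg/s; positive = rotation toward
#'   the implanted side, the "on" stimulation direction).
#' @param mapping A [build_mapping()] object.
#' @return The input tibble with added columns `linear_rate_pps` (pre-sigmoid)
#'   and `final_rate_pps` (post-sigmoid), plus attributes `sample_rate`,
#'   `warmup_s` and `mapping`.
#' @examples
#' head <- make_stimulus(stimulus_spec("sinusoid", frequency = 1))
#' enc <- encode_head_velocity(head, build_mapping("static"))
#' range(enc$final_rate_pps)
#' @export
encode_head_velocity <- function(head, mapping) {
  stopifnot(inherits(mapping, "vp_mapping"), is.data.frame(head))
  if (nrow(head) == 0L) stop("empty head-velocity series", call. = FALSE)
  if (!all(c("time_s", "head_vel_dps") %in% names(head))) {
    stop("`head` needs columns `time_s` and `head_vel_dps`", call. = FALSE)
  }
  stopifnot(all(is.finite(head$head_vel_dps)))
  fs <- attr(head, "sample_rate") %||% infer_fs(head$time_s)
  mod <- mapping_filter(mapping, head$head_vel_dps, fs)
  out <- tibble::as_tibble(head)
  out$linear_rate_pps <- mod + mapping$r0
  out$final_rate_pps <- apply_sigmoid(out$linear_rate_pps, mapping$sigmoid)
  attr(out, "sample_rate") <- fs
  attr(out, "warmup_s") <- mapping_warmup(mapping)
  attr(out, "mapping") <- mapping
  attr(out, "stimulus") <- attr(head, "stimulus")
  out
}

#' Convert a pulse-rate series into discrete pulse times
#'
#' Deterministic integrate-to-threshold pulse generation: the post-sigmoid
#' rate is integrated over time and a pulse is emitted each time the integral
#' crosses the next integer (reset by subtraction). Crossing times are
#' linearly interpolated within a sample, so the reconstructed rate (1/ISI)
#' tracks the commanded rate to well within one sample period.
#'
#' @param rates Output of [encode_head_velocity()] (needs `time_s` and
#'   `final_rate_pps`).
#' @return A tibble with one column `pulse_time_s`, strictly increasing.
#' @examples
#' head <- tibble::tibble(time_s = (0:999) / 1000, head_vel_dps = 0)
#' pt <- rate_to_pulse_times(encode_head_velocity(head, build_mapping("static")))
#' nrow(pt)  # 150 pulses in 1 s at the 150 pps baseline
#' @export
rate_to_pulse_times <- function(rates) {
  stopifnot(is.data.frame(rates),
            all(c("time_s", "final_rate_pps") %in% names(rates)))
  fs <- attr(rates, "sample_rate") %||% infer_fs(rates$time_s)
  ci <- cumsum(rates$final_rate_pps) / fs
  n_pulses <- floor(ci[length(ci)])
  if (n_pulses < 1) return(tibble::tibble(pulse_time_s = numeric()))
  times <- stats::approx(x = c(0, ci), y = c(rates$time_s[1] - 1 / fs, rates$time_s),
                         xout = seq_len(n_pulses), ties = "ordered")$y
  tibble::tibble(pulse_time_s = times)
}
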