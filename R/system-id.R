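#' Fit a rational transfer function to a frequency response
#'
#' Weighted complex least-squares fit of a continuous-domain rational
#' transfer function `B(s)/A(s)` (with `n_zeros` zeros and `n_poles` poles)
#' to measured gain/phase data, with Sanathanan-Koerner iterative reweighting
#' (weights `1/|A_prev(i w)|^2`) until the coefficient change falls below
#' `tol` or `max_iter` iterations. The fixed pathway delay is handled outside
#' the rational part: the measured phase is advanced by `delay` before
#' fitting, and [predict_response()] re-applies the delay. Unstable poles of
#' the converged fit are reflected into the left half-plane.
#'
#' @param response A data frame with columns `frequency_hz`, `gain`, and
#'   `phase_deg` (phase lead positive).
#' @param n_zeros,n_poles Orders of the numerator and denominator
#'   (`n_poles >= n_zeros`); at least `n_zeros + n_poles + 1` frequencies are
#'   required.
#' @param delay Fixed delay (s), default 0.006.
#' @param max_iter,tol Iteration controls.
#' @return An object of class `vp_tf`: `zeros`, `poles`, `gain` (leading
#'   numerator coefficient), `delay`, `converged`, `iterations`, and the
#'   fitting data.
#' @examples
#' resp <- vor_chain_response(vor_params("monkey_Y_like"),
#'                            c(0.2, 0.5, 1, 2, 5, 10, 20))
#' fit_rational_tf(resp, n_zeros = 2, n_poles = 3)
#' @export
fit_rational_tf <- function(response, n_zeros, n_poles, delay = 0.006,
                            max_iter = 50L, tol = 1e-8) {
  stopifnot(is.data.frame(response),
            all(c("frequency_hz", "gain", "phase_deg") %in% names(response)),
            n_poles >= n_zeros, n_zeros >= 0)
  if (nrow(response) < n_zeros + n_poles + 1) {
    stop("need at least ", n_zeros + n_poles + 1, " frequencies for a (",
         n_zeros, ", ", n_poles, ") fit; got ", nrow(response), call. = FALSE)
  }
  if (any(response$gain <= 0)) stop("gains must be positive", call. = FALSE)
  w <- 2 * pi * response$frequency_hz
  s <- 1i * w
  # remove the fixed delay before fitting
  g <- response$gain * exp(1i * (response$phase_deg * pi / 180 + w * delay))

  pow <- function(ex) vapply(ex, function(p) s^p, complex(length(s)))
  Xb <- pow(seq(n_zeros, 0))                     # columns s^nz ... s^0
  Xa <- if (n_poles > 0) -g * pow(seq(n_poles - 1, 0)) else NULL
  rhs <- g * s^n_poles
  coef <- rep(0, n_zeros + 1 + n_poles)
  a_prev <- c(1, rep(0, n_poles))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    wt <- 1 / Mod(polyval_c(a_prev, s))
    X <- cbind(Xb, Xa) * wt
    y <- rhs * wt
    fit <- stats::lm.fit(rbind(Re(X), Im(X)), c(Re(y), Im(y)))
    new_coef <- unname(fit$coefficients)
    new_coef[is.na(new_coef)] <- 0
    a_prev <- c(1, new_coef[n_zeros + 1 + seq_len(n_poles)])
    if (max(abs(new_coef - coef)) < tol * (1 + max(abs(new_coef)))) {
      coef <- new_coef
      converged <- TRUE
      break
    }
    coef <- new_coef
  }
  if (!converged) {
    warning("rational fit did not converge in ", max_iter,
            " iterations; returning last iterate")
  }
  b <- coef[seq_len(n_zeros + 1)]
  a <- c(1, coef[n_zeros + 1 + seq_len(n_poles)])
  zeros <- if (n_zeros > 0) polyroot(rev(b)) else complex(0)
  poles <- if (n_poles > 0) polyroot(rev(a)) else complex(0)
  poles <- ifelse(Re(poles) > 0, complex(real = -Re(poles),
                                         imaginary = Im(poles)), poles)
  structure(
    list(zeros = zeros, poles = poles, gain = b[1], delay = delay,
         n_zeros = n_zeros, n_poles = n_poles, converged = converged,
         iterations = iter, response = tibble::as_tibble(response)),
    class = "vp_tf"
  )
}

#' Frequency response from pulse-rate modulation to eye velocity
#'
#' Builds the input-output table for [fit_rational_tf()] from analysed
#' sinusoidal recordings: for each recording, the slow-phase eye velocity and
#' the commanded pulse-rate modulation (about the baseline rate) are
#' projected onto the stimulus fundamental over post-warm-up complete cycles,
#' and their complex ratio gives the gain and phase at that frequency. Using
#' pulse-rate modulation as the input domain lets one model predict the
#' responses to every mapping, since all nonlinearity (the sigmoid) sits
#' upstream of the pulse rate.
#'
#' @param recordings A list of [preprocess_eye()] outputs of sinusoidal
#'   recordings (must retain the `pulse_rate_pps` column).
#' @param r0 Baseline pulse rate (pps).
#' @return A tibble `frequency_hz`, `gain` ((deg/s) per pps), `phase_deg`.
#' @export
pulse_rate_response <- function(recordings, r0 = 150) {
  stopifnot(is.list(recordings), length(recordings) >= 1L)
  purrr::map_dfr(recordings, function(rec) {
    st <- attr(rec, "stimulus")
    stopifnot(inherits(st, "vp_stimulus"), st$type == "sinusoid",
              "pulse_rate_pps" %in% names(rec))
    f <- st$frequency
    warmup <- attr(rec, "warmup_s") %||% 0
    use <- rec$time_s >= ceiling(warmup * f) / f
    fs <- attr(rec, "sample_rate") %||% infer_fs(rec$time_s)
    ce <- fundamental_complex(rec$eye_vel_dps, rec$time_s, f,
                              use & rec$slow_phase)
    cr <- fundamental_complex(rec$pulse_rate_pps - r0, rec$time_s, f, use)
    # deconvolve the known zero-phase measurement-filter response
    h <- ce / preproc_chain_gain(f, fs) / cr
    tibble::tibble(frequency_hz = f, gain = Mod(h),
                   phase_deg = Arg(h) * 180 / pi)
  })
}

#' @export
print.vp_tf <- function(x, ...) {
  cat("<vp_tf> ", x$n_zeros, " zero(s), ", x$n_poles, " pole(s), delay ",
      x$delay * 1000, " ms\n", sep = "")
  cat("  gain:", signif(Re(x$gain), 6), "\n")
  if (length(x$zeros)) cat("  zeros:", paste(signif(x$zeros, 5), collapse = ", "), "\n")
  if (length(x$poles)) cat("  poles:", paste(signif(x$poles, 5), collapse = ", "), "\n")
  cat(if (x$converged) "  converged in" else "  NOT converged after",
      x$iterations, "iterations\n")
  invisible(x)
}

#' Frequency response of a fitted rational transfer function
#'
#' @param model A `vp_tf` from [fit_rational_tf()].
#' @param frequencies Frequencies (Hz).
#' @param apply_delay Include the fixed delay's phase lag (default `TRUE`).
#' @return A tibble `frequency_hz`, `gain`, `phase_deg`, `response`.
#' @export
tf_frequency_response <- function(model, frequencies, apply_delay = TRUE) {
  stopifnot(inherits(model, "vp_tf"))
  h <- ct_freq_response(model$zeros, model$poles, model$gain, frequencies)
  if (apply_delay) h <- h * exp(-1i * 2 * pi * frequencies * model$delay)
  tibble::tibble(frequency_hz = frequencies, gain = Mod(h),
                 phase_deg = Arg(h) * 180 / pi, response = h)
}

#' Predict a time-domain response from a fitted transfer function
#'
#' Discrete simulation (bilinear transform at the series sample rate) of the
#' fitted rational transfer function, followed by the fixed delay as an
#' integer-sample shift. The default input domain is commanded pulse-rate
#' modulation about baseline.
#'
#' @param model A stable `vp_tf`.
#' @param input A data frame with `time_s` and the input column.
#' @param col Name of the input column (default `"rate_mod_pps"`, falling
#'   back to the first non-time numeric column).
#' @return The input tibble with an added `predicted` column.
#' @export
predict_response <- function(model, input, col = NULL) {
  stopifnot(inherits(model, "vp_tf"), is.data.frame(input),
            "time_s" %in% names(input))
  if (any(Re(model$poles) >= 0)) {
    stop("model has unstable poles; cannot simulate", call. = FALSE)
  }
  col <- col %||% intersect(c("rate_mod_pps", "afferent_mod_sps"),
                            names(input))[1]
  if (is.na(col) || is.null(col)) {
    col <- setdiff(names(input), "time_s")[1]
  }
  fs <- attr(input, "sample_rate") %||% infer_fs(input$time_s)
  y <- ct_filter(input[[col]], model$zeros, model$poles, Re(model$gain), fs)
  out <- tibble::as_tibble(input)
  out$predicted <- delay_shift(y, round(model$delay * fs))
  attr(out, "sample_rate") <- fs
  out
}

#' Variance accounted for
#'
#' `VAF = 1 - Var(y - yhat) / Var(y)`. Equals 1 iff the prediction is exact
#' (up to a constant-free residual) and can be negative for predictions worse
#' than the observed mean.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return A scalar.
#' @examples
#' vaf(sin(1:100), sin(1:100))  # 1
#' @export
vaf <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` differ in length", call. = FALSE)
  }
  v <- stats::var(observed)
  if (!is.finite(v) || v == 0) {
    stop("`observed` has zero variance; VAF undefined", call. = FALSE)
  }
  1 - stats::var(observed - predicted) / v
}

#' Estimate stimulation efficacy from peak-velocity observations
#'
#' The forward model's eye velocity is linear in the stimulation efficacy, so
#' the efficacy that best explains observed maximum eye velocities across
#' stimulation conditions is found by bounded scalar minimization of the
#' summed squared error between model-predicted and observed maxima over
#' efficacy in (0, 1]. With `depression_variant = TRUE` the model output is
#' rescaled by 0.83 (17% central-pathway depression) before fitting, which
#' yields a correspondingly larger efficacy estimate.
#'
#' @param observations A data frame with list-columns `mapping` and
#'   `stimulus` (as for [peak_velocity_curve()]) and a column
#'   `max_eye_vel_dps` of observed peak velocities. At least 3 conditions
#'   spanning at least 2 frequencies are required.
#' @param params A [vor_params()] object; its `efficacy` and `depression`
#'   fields are overridden during fitting.
#' @param depression_variant Include the 17% central depression.
#' @return An object of class `vp_efficacy_fit` with fields `efficacy`,
#'   `depression_variant`, `objective`, and a per-condition `table` of
#'   predicted vs observed maxima.
#' @export
estimate_efficacy <- function(observations, params, depression_variant = FALSE) {
  stopifnot(is.data.frame(observations),
            all(c("mapping", "stimulus", "max_eye_vel_dps") %in%
                  names(observations)))
  if (nrow(observations) < 3L) {
    stop("need at least 3 conditions", call. = FALSE)
  }
  freqs <- vapply(observations$stimulus,
                  function(s) s$frequency %||% NA_real_, numeric(1))
  if (length(unique(stats::na.omit(freqs))) < 2L) {
    stop("observations must span at least 2 frequencies", call. = FALSE)
  }
  if (all(observations$max_eye_vel_dps == 0)) {
    stop("degenerate observations: all peak velocities are zero", call. = FALSE)
  }
  base_params <- params
  base_params$efficacy <- 1
  base_params$depression <- 0
  base <- peak_velocity_curve(
    dplyr::select(observations, "mapping", "stimulus"), base_params)
  pred0 <- base$max_eye_vel_dps * (if (depression_variant) 1 - 0.17 else 1)
  obs <- observations$max_eye_vel_dps
  sse <- function(e) sum((e * pred0 - obs)^2)
  opt <- stats::optimize(sse, interval = c(1e-6, 1), tol = 1e-6)
  # the objective is quadratic in efficacy: snap to the closed-form optimum
  # when it lies inside the bounds (optimize() alone stops at its tolerance)
  e_ls <- sum(pred0 * obs) / sum(pred0^2)
  efficacy <- if (e_ls > 1e-6 && e_ls <= 1) e_ls else opt$minimum
  structure(
    list(efficacy = efficacy, depression_variant = depression_variant,
         objective = sse(efficacy),
         table = tibble::tibble(
           frequency_hz = base$frequency_hz,
           max_rate_pps = base$max_rate_pps,
           observed_dps = obs,
           predicted_dps = efficacy * pred0
         )),
    class = "vp_efficacy_fit"
  )
}

#' @export
print.vp_efficacy_fit <- function(x, ...) {
  cat("<vp_efficacy_fit> efficacy:", signif(x$efficacy, 4),
      if (x$depression_variant) "(with 17% central depression)", "\n")
  cat("  SSE:", signif(x$objective, 4), "over", nrow(x$table), "conditions\n")
  invisible(x)
}

#' Sigmoid saturation diagnostic
#'
#' For each mapping/gain condition, encodes the stimulus and compares the
#' peak pre-sigmoid (linear-stage) pulse rate with the peak post-sigmoid
#' rate. Conditions whose post/pre peak ratio falls below `threshold`
#' (default 0.9) are flagged as saturating — i.e., the rate-limiting sigmoid,
#' not the mapping dynamics, is shaping their output.
#'
#' @param conditions A data frame with a list-column `mapping`
#'   ([build_mapping()] objects); other columns are carried through.
#' @param stimulus A [stimulus_spec()] applied to every condition.
#' @param threshold Post/pre ratio below which a condition is flagged.
#' @param bypass_sigmoid If `TRUE`, the post-sigmoid rate is replaced by the
#'   linear rate (all ratios become exactly 1); a control setting.
#' @return The input tibble with `pre_peak_pps`, `post_peak_pps`, `ratio`,
#'   `saturating` columns.
#' @export
saturation_diagnostic <- function(conditions, stimulus, threshold = 0.9,
                                  bypass_sigmoid = FALSE) {
  stopifnot(is.data.frame(conditions), "mapping" %in% names(conditions),
            inherits(stimulus, "vp_stimulus"))
  head <- make_stimulus(stimulus)
  res <- purrr::map_dfr(conditions$mapping, function(m) {
    enc <- encode_head_velocity(head, m)
    keep <- enc$time_s >= attr(enc, "warmup_s")
    if (!any(keep)) keep <- rep(TRUE, nrow(enc))
    pre <- max(enc$linear_rate_pps[keep])
    post <- if (bypass_sigmoid) pre else max(enc$final_rate_pps[keep])
    tibble::tibble(pre_peak_pps = pre, post_peak_pps = post,
                   ratio = post / pre)
  })
  out <- dplyr::bind_cols(tibble::as_tibble(conditions), res)
  out$saturating <- out$ratio < threshold
  out
}
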