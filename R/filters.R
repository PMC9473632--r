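# Internal continuous-/discrete-time filtering helpers shared by the encoder,
# the VOR forward model and the system-identification code.

# polynomial coefficients (descending powers) from roots
poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p) * ri
  p
}

# evaluate a polynomial (descending coefficients) at complex s
polyval_c <- function(coef, s) {
  out <- rep(0 + 0i, length(s))
  for (cf in coef) out <- out * s + cf
  out
}

# H(i*2*pi*f) for a continuous-time zero/pole/gain system
ct_freq_response <- function(zeros, poles, gain, f) {
  s <- 1i * 2 * pi * f
  num <- rep(gain + 0i, length(s))
  for (z in zeros) num <- num * (s - z)
  den <- rep(1 + 0i, length(s))
  for (p in poles) den <- den * (s - p)
  num / den
}

# Discretize a continuous-time zpk system with the bilinear transform at
# sample rate fs and filter x through it (one-pass, causal, zero initial state).
ct_filter <- function(x, zeros, poles, gain, fs) {
  if (length(poles) == 0L && length(zeros) == 0L) return(gain * x)
  zp <- signal::bilinear(Sz = zeros, Sp = poles, Sg = gain, T = 1 / fs)
  b <- Re(zp$gain * poly_from_roots(zp$zero))
  a <- Re(poly_from_roots(zp$pole))
  as.numeric(signal::filter(b, a, x))
}

# Pure delay as an integer-sample shift; the head of the output is held at
# the first sample value (series are assumed to start at rest).
delay_shift <- function(x, n_samples) {
  n_samples <- as.integer(round(n_samples))
  if (n_samples <= 0L) return(x)
  n <- length(x)
  if (n_samples >= n) return(rep(x[1], n))
  c(rep(x[1], n_samples), x[seq_len(n - n_samples)])
}

# Hamming-window FIR low-pass coefficients, normalized to exactly unit DC gain
fir_lp_coef <- function(fs, cutoff, taps = 51L) {
  b <- as.numeric(signal::fir1(taps - 1L, cutoff / (fs / 2), type = "low",
                               window = signal::hamming(taps)))
  b / sum(b)
}

# Zero-phase FIR low-pass (Hamming window, `taps` coefficients) at `cutoff` Hz.
fir_lowpass <- function(x, fs, cutoff, taps = 51L) {
  if (length(x) <= 3L * taps) {
    stop("series too short for a ", taps, "-tap zero-phase filter", call. = FALSE)
  }
  as.numeric(signal::filtfilt(fir_lp_coef(fs, cutoff, taps), 1, x))
}

# Amplitude response of the standard preprocessing chain at frequency f:
# zero-phase 125 Hz FIR on position (magnitude squared by filtfilt),
# central-difference differentiation, zero-phase 50 Hz FIR on velocity.
# Known exactly, so cycle fits can deconvolve it.
preproc_chain_gain <- function(f, fs, taps = 51L) {
  z <- exp(-1i * 2 * pi * f / fs)
  h125 <- Mod(polyval_c(rev(fir_lp_coef(fs, 125, taps)), z))^2
  h50 <- Mod(polyval_c(rev(fir_lp_coef(fs, 50, taps)), z))^2
  wT <- 2 * pi * f / fs
  diff_gain <- sin(wT) / wT
  h125 * h50 * diff_gain
}

# Least-squares fit of a*sin(2*pi*f*t) + b*cos(2*pi*f*t) + c on a subset of
# samples (use = logical mask). Returns c(a, b, offset).
fit_sincos <- function(x, t, f, use = NULL) {
  if (!is.null(use)) {
    x <- x[use]
    t <- t[use]
  }
  s <- sin(2 * pi * f * t)
  cc <- cos(2 * pi * f * t)
  cf <- stats::lm.fit(cbind(s, cc, 1), x)$coefficients
  c(a = unname(cf[1]), b = unname(cf[2]), offset = unname(cf[3]))
}

# Complex fundamental (a - i b corresponds to amplitude*exp(i*phase) for a
# sin-reference) of x at frequency f over the samples selected by `use`.
fundamental_complex <- function(x, t, f, use = NULL) {
  cf <- fit_sincos(x, t, f, use)
  complex(real = cf[["a"]], imaginary = cf[["b"]])
}

# infer sample rate from a time column (uniform grid assumed)
infer_fs <- function(time_s) {
  dt <- stats::median(diff(time_s))
  if (!is.finite(dt) || dt <= 0) stop("cannot infer sample rate from `time_s`",
                                      call. = FALSE)
  1 / dt
}

# run a function with a locally-seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
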