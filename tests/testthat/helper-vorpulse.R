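# Shared fixtures and independent oracles.

# Independent frequency-domain oracle for the afferent-style transfer
# function H(f) = k S (S + 1/T1) / ((S + 1/Tc)(S + 1/T2)), S = i 2 pi f.
# Written with raw complex arithmetic, independent of the package's
# zero/pole/gain evaluation path.
oracle_tf <- function(k, T1, T2, Tc, f) {
  S <- 1i * 2 * pi * f
  k * S * (S + 1 / T1) / ((S + 1 / Tc) * (S + 1 / T2))
}

# Independent steady-state projection: amplitude and phase (deg, sin
# reference) of x at frequency f over the last `n_cycles` complete cycles,
# using the orthogonality of sin/cos on complete cycles (no regression).
oracle_sine_fit <- function(x, t, f, n_cycles) {
  fs <- 1 / (t[2] - t[1])
  len <- round(n_cycles * fs / f)
  idx <- (length(x) - len + 1):length(x)
  a <- 2 * mean(x[idx] * sin(2 * pi * f * t[idx]))
  b <- 2 * mean(x[idx] * cos(2 * pi * f * t[idx]))
  list(amplitude = sqrt(a^2 + b^2), phase_deg = atan2(b, a) * 180 / pi)
}

paper_frequencies <- c(0.2, 0.5, 1, 2, 5, 10, 20)

quiet_noise <- noise_spec(position_noise_sd = 0, saccade_rate = 0)

params_y <- function(efficacy = 1, ...) {
  vor_params("monkey_Y_like", efficacy = efficacy, ...)
}
params_g <- function(efficacy = 1, ...) {
  vor_params("monkey_G_like", efficacy = efficacy, ...)
}

# head-velocity tibble on a uniform grid
head_series <- function(v, fs = 1000) {
  out <- tibble::tibble(time_s = (seq_along(v) - 1) / fs, head_vel_dps = v)
  attr(out, "sample_rate") <- fs
  out
}

# long steady-state sinusoid with generous settling time for oracle checks
steady_sinusoid <- function(f, peak = 50, settle_s = 20, n_cycles = 10,
                            fs = 1000) {
  t <- seq(0, settle_s + n_cycles / f, by = 1 / fs)
  head_series(peak * sin(2 * pi * f * t), fs)
}
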