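test_that("preprocessing differentiates and preserves in-band content", {
  fs <- 1000
  t <- (0:9999) / fs
  A <- 2
  rec <- tibble::tibble(time_s = t, eye_pos_deg = A * sin(2 * pi * 1 * t))
  attr(rec, "sample_rate") <- fs
  pe <- preprocess_eye(rec)
  mid <- t > 1 & t < 9
  est <- oracle_sine_fit(pe$eye_vel_dps[mid], t[mid], 1, 7)
  # d/dt A sin(wt) = A w cos(wt): amplitude 2 pi A, 90 deg lead
  expect_equal(est$amplitude, 2 * pi * A, tolerance = 1e-3)
  expect_equal(est$phase_deg, 90, tolerance = 0.05)
  expect_true(all(pe$slow_phase[mid]))

  # constant-velocity segment passes through the DC passband unchanged
  rec2 <- tibble::tibble(time_s = t, eye_pos_deg = 5 * t)
  attr(rec2, "sample_rate") <- fs
  pe2 <- preprocess_eye(rec2)
  expect_equal(pe2$eye_vel_dps[mid], rep(5, sum(mid)), tolerance = 1e-6)

  expect_error(preprocess_eye(tibble::tibble(time_s = (0:99) / fs,
                                             eye_pos_deg = rnorm(100))),
               "too short")
})

test_that("injected saccades are detected and flagged, not smeared", {
  st <- stimulus_spec("sinusoid", frequency = 2, n_cycles = 20)
  mp <- build_mapping("regular")
  p <- params_y(efficacy = 0.28)
  rec <- synthesize_recording(st, mp, p,
                              noise_spec(position_noise_sd = 0,
                                         saccade_rate = 0.5, seed = 21))
  truth <- attr(rec, "truth")
  expect_gt(nrow(truth$saccades), 0)
  pe <- preprocess_eye(rec)
  inj <- rep(FALSE, nrow(rec))
  for (i in seq_len(nrow(truth$saccades))) {
    inj[rec$time_s >= truth$saccades$start_s[i] &
          rec$time_s <= truth$saccades$end_s[i]] <- TRUE
  }
  # at least 95% of injected saccade samples fall inside detected intervals
  expect_gte(mean(!pe$slow_phase[inj]), 0.95)

  # detection/masking does not alter slow-phase samples away from saccades:
  # the same recording without saccades preprocesses to identical velocity
  rec0 <- synthesize_recording(st, mp, p,
                               noise_spec(position_noise_sd = 0,
                                          saccade_rate = 0, seed = 21))
  pe0 <- preprocess_eye(rec0)
  far <- rec$time_s > 0.3 & rec$time_s < max(rec$time_s) - 0.3
  for (i in seq_len(nrow(truth$saccades))) {
    far <- far & (rec$time_s < truth$saccades$start_s[i] - 0.15 |
                    rec$time_s > truth$saccades$end_s[i] + 0.15)
  }
  expect_equal(pe$eye_vel_dps[far], pe0$eye_vel_dps[far], tolerance = 1e-6)
})

test_that("cycle fits recover a constructed response exactly", {
  # eye = -0.6 * head shifted by +10 deg of phase: gain 0.600, phase +10.0
  f <- 1
  fs <- 1000
  st <- stimulus_spec("sinusoid", frequency = f, n_cycles = 10)
  t <- (0:9999) / fs
  vel <- tibble::tibble(
    time_s = t,
    eye_vel_dps = -0.6 * 50 * sin(2 * pi * f * t + 10 * pi / 180),
    slow_phase = TRUE
  )
  attr(vel, "sample_rate") <- fs
  fits <- fit_cycles(vel, st, skip_s = 0, compensate_filters = FALSE)
  expect_equal(nrow(fits), 10)
  expect_equal(fits$gain, rep(0.6, 10), tolerance = 1e-9)
  expect_equal(fits$phase_deg, rep(10, 10), tolerance = 1e-9)
  expect_true(all(fits$included))
})

test_that("cycle inclusion rules follow the slow-phase thresholds", {
  f <- 0.5
  fs <- 1000
  st <- stimulus_spec("sinusoid", frequency = f, n_cycles = 4)
  t <- (0:7999) / fs
  vel <- tibble::tibble(time_s = t,
                        eye_vel_dps = -25 * sin(2 * pi * f * t),
                        slow_phase = TRUE)
  attr(vel, "sample_rate") <- fs
  # mask 70% of the second cycle: 30% slow phase < 40% threshold -> excluded
  vel$slow_phase[t >= 2 & t < 3.4] <- FALSE
  fits <- fit_cycles(vel, st, skip_s = 0)
  expect_false(fits$included[2])
  expect_true(all(fits$included[-2]))

  # 9 included cycles at 5 Hz: summary refuses (needs >= 10)
  st5 <- stimulus_spec("sinusoid", frequency = 5, n_cycles = 9)
  t5 <- (0:(9 * 200 - 1)) / fs
  vel5 <- tibble::tibble(time_s = t5,
                         eye_vel_dps = -25 * sin(2 * pi * 5 * t5),
                         slow_phase = TRUE)
  attr(vel5, "sample_rate") <- fs
  fits5 <- fit_cycles(vel5, st5, skip_s = 0)
  expect_equal(sum(fits5$included), 9)
  expect_error(summarize_response(fits5), "insufficient cycles")
})

test_that("summary scalars behave as defined", {
  mk_fits <- function(freqs, gains, n = 12) {
    purrr::map2_dfr(freqs, gains, function(f, g) {
      tibble::tibble(cycle = seq_len(n), frequency_hz = f, gain = g,
                     phase_deg = if (f == 10) -10 else 10,
                     offset_dps = 0, slow_phase_fraction = 1, included = TRUE)
    })
  }
  up <- summarize_response(mk_fits(c(5, 10, 20), c(1, 2, 4)))
  expect_gt(glance(up)$log_gain_slope, 0)
  down <- summarize_response(mk_fits(c(5, 10, 20), c(4, 2, 1)))
  expect_lt(glance(down)$log_gain_slope, 0)
  # per-frequency phases of +10, -10, +10 deg -> mean absolute phase 10
  expect_equal(glance(up)$mean_abs_phase_hf, 10)

  # x2 cycle gains exactly double -> ratio 2 at every frequency
  x1 <- mk_fits(c(5, 10, 20), c(1, 2, 4))
  x2 <- mk_fits(c(5, 10, 20), c(2, 4, 8))
  s <- summarize_response(x1, fits_x2 = x2)
  expect_equal(s$gain_ratio, rep(2, 3))

  # normalization against a reference table
  ref <- tibble::tibble(frequency_hz = c(5, 10, 20), mean_gain = c(1, 1, 2))
  sn <- summarize_response(x1, normalize_by = ref)
  expect_equal(sn$norm_gain, c(1, 2, 2))
})

test_that("bootstrap phase SE matches analytic expectations", {
  same <- tibble::tibble(cycle = 1:20, frequency_hz = 2, gain = 0.5,
                         phase_deg = 7, offset_dps = 0,
                         slow_phase_fraction = 1, included = TRUE)
  expect_equal(bootstrap_phase_se(same, 200, seed = 1), 0)

  set.seed(5)
  sigma <- 4
  gauss <- tibble::tibble(cycle = 1:200, frequency_hz = 2, gain = 0.5,
                          phase_deg = rnorm(200, 0, sigma), offset_dps = 0,
                          slow_phase_fraction = 1, included = TRUE)
  se <- bootstrap_phase_se(gauss, 2000, seed = 2)
  expect_equal(se, sigma / sqrt(200), tolerance = 0.15)

  # determinism under a fixed seed
  expect_identical(bootstrap_phase_se(gauss, 500, seed = 3),
                   bootstrap_phase_se(gauss, 500, seed = 3))
  expect_error(bootstrap_phase_se(same[0, ]), "no included cycles")
})

test_that("transient metrics recover the programmed delay and definitions", {
  p <- params_y(efficacy = 0.28)
  mp <- build_mapping("regular")
  st <- stimulus_spec("transient")
  trials <- lapply(1:4, function(i)
    preprocess_eye(synthesize_recording(st, mp, p, quiet_noise,
                                        asymmetry = 1)))
  tm <- transient_metrics(trials, st)
  expect_equal(tm$latency_ms, p$tau * 1000, tolerance = 2)
  expect_equal(tm$n_trials, 4)

  # gain is peak |eye| / peak |head|
  peak_eye <- max(abs(trials[[1]]$eye_vel_dps[trials[[1]]$time_s > 0.3]))
  expect_equal(tm$gain, peak_eye / 200, tolerance = 0.01)

  # latency estimator is translation-equivariant
  st_late <- stimulus_spec("transient", pre_pad_s = 0.45)
  trials_late <- lapply(1:4, function(i)
    preprocess_eye(synthesize_recording(st_late, mp, p, quiet_noise,
                                        asymmetry = 1)))
  tm_late <- transient_metrics(trials_late, st_late)
  expect_equal(tm_late$latency_ms, tm$latency_ms, tolerance = 0.5)

  # a trial with a saccade just before onset is excluded
  sacc_trial <- trials[[1]]
  attr(sacc_trial, "saccades") <- tibble::tibble(start_s = 0.27, end_s = 0.29)
  expect_error(transient_metrics(list(sacc_trial, trials[[2]], trials[[3]],
                                      trials[[4]]), st),
               "insufficient trials")
})

test_that("baseline subtraction isolates the prosthesis-evoked component", {
  t <- (0:999) / 1000
  base <- tibble::tibble(time_s = t, eye_vel_dps = 3 * sin(2 * pi * 3 * t))
  extra <- 5 * sin(2 * pi * 2 * t + 0.4)
  cond <- tibble::tibble(time_s = t, eye_vel_dps = base$eye_vel_dps + extra)
  out <- subtract_baseline(cond, base)
  expect_equal(out$eye_vel_dps, extra)
  expect_equal(subtract_baseline(base, base)$eye_vel_dps, rep(0, 1000))
  expect_error(subtract_baseline(cond[1:10, ], base), "length")
})
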