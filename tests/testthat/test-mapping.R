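test_that("mapping registry reproduces the printed constants", {
  reg <- build_mapping("regular")
  expect_equal(reg$k, 5.056)
  expect_equal(reg$T1, 0.0175)
  expect_equal(reg$T2, 0.0027)
  expect_equal(reg$Tc, 5.7)

  irr <- build_mapping("irregular")
  expect_equal(irr$k, 38.889)
  expect_equal(irr$T1, 0.03)
  expect_equal(irr$T2, 0.0006)

  shp <- build_mapping("super_high_pass")
  expect_equal(shp$k, 76.76)
  expect_equal(shp$T1, 0.06)

  expect_equal(build_mapping("mixed")$n, 1.5923)
  expect_equal(build_mapping("static")$flat_gain, 0.78)

  # the x2 condition doubles only the overall gain constant
  expect_equal(build_mapping("regular", 2)$k, 2 * 5.056)
  expect_equal(build_mapping("regular", 2)$T1, 0.0175)
  expect_equal(build_mapping("mixed", 2)$n, 3.1846)
  expect_equal(build_mapping("static", 2)$flat_gain, 1.56)

  expect_error(build_mapping("bogus"), "valid kinds")
  expect_error(build_mapping("regular", 3), "gain_multiplier")
})

test_that("sigmoid has the stated fixed point, bound, and slopes", {
  sg <- sigmoid_spec()
  expect_equal(sg$c1, 4 / 500)
  expect_equal(sg$c2, 150 + log(500 / 150 - 1) / (4 / 500))

  expect_equal(apply_sigmoid(150, sg), 150)
  expect_equal(apply_sigmoid(1e6, sg), 500)
  expect_equal(apply_sigmoid(sg$c2, sg), 250)

  # max slope at the inflection point is c1*c3/4 = 1; slope at baseline 0.84
  h <- 1e-5
  slope_mid <- (apply_sigmoid(sg$c2 + h, sg) - apply_sigmoid(sg$c2 - h, sg)) /
    (2 * h)
  slope_base <- (apply_sigmoid(150 + h, sg) - apply_sigmoid(150 - h, sg)) /
    (2 * h)
  expect_equal(slope_mid, 1, tolerance = 1e-8)
  expect_equal(slope_base, 0.84, tolerance = 1e-6)
})

test_that("sigmoid is bounded and monotone over a wide input range", {
  sg <- sigmoid_spec()
  x <- seq(-1e4, 1e4, length.out = 4001)
  y <- apply_sigmoid(x, sg)
  expect_true(all(y > 0 & y <= 500))
  expect_true(all(diff(y) >= 0))
  # the bound is strict wherever the gap is representable in double precision
  xm <- seq(-2000, 2000, length.out = 801)
  expect_true(all(apply_sigmoid(xm, sg) < 500))
})

test_that("analytic frequency responses match the independent oracle", {
  for (kind in c("regular", "irregular", "super_high_pass")) {
    m <- build_mapping(kind)
    fr <- mapping_frequency_response(m, paper_frequencies)
    h <- oracle_tf(m$k, m$T1, m$T2, m$Tc, paper_frequencies)
    expect_equal(fr$gain_pps_per_dps, Mod(h), tolerance = 1e-12)
    expect_equal(fr$phase_deg, Arg(h) * 180 / pi, tolerance = 1e-12)
  }
  # mixed is the rescaled mean of the two component responses
  mx <- build_mapping("mixed")
  hr <- oracle_tf(5.056, 0.0175, 0.0027, 5.7, paper_frequencies)
  hi <- oracle_tf(38.889, 0.03, 0.0006, 5.7, paper_frequencies)
  fr <- mapping_frequency_response(mx, paper_frequencies)
  expect_equal(fr$gain_pps_per_dps, Mod(1.5923 * (hr + hi) / 2),
               tolerance = 1e-12)
})

test_that("frequency-response worked examples hold", {
  fr_static <- mapping_frequency_response(build_mapping("static"), c(0.3, 7, 20))
  expect_equal(fr_static$gain_pps_per_dps, rep(0.78, 3))
  expect_equal(fr_static$phase_deg, rep(0, 3))

  fr_reg <- mapping_frequency_response(build_mapping("regular"), c(0.5, 20))
  expect_equal(fr_reg$gain_pps_per_dps[1], 0.780, tolerance = 1e-3)
  expect_equal(fr_reg$phase_deg[1], 5.9, tolerance = 0.01)
  # at least the 2-fold modulation increase at 20 vs 0.5 Hz
  ratio <- fr_reg$gain_pps_per_dps[2] / fr_reg$gain_pps_per_dps[1]
  expect_gte(ratio, 2)
  expect_equal(ratio, 2.29, tolerance = 1e-3)

  fr_shp <- mapping_frequency_response(build_mapping("super_high_pass"), 20)
  expect_equal(fr_shp$gain_pps_per_dps, 5.82, tolerance = 1e-3)

  expect_error(mapping_frequency_response(build_mapping("regular"), c(1, -2)),
               "positive")
})

test_that("mixed-mapping renormalization matches the 0.5 Hz static gain", {
  # printed n leaves the 0.5 Hz gain well above 0.78 (the constants are
  # mutually inconsistent); the renormalized variant pins it exactly
  g_printed <- mapping_frequency_response(build_mapping("mixed"), 0.5)
  expect_equal(g_printed$gain_pps_per_dps, 1.24, tolerance = 0.01)
  g_renorm <- mapping_frequency_response(
    build_mapping("mixed", renormalize_mixed = TRUE), 0.5)
  expect_equal(g_renorm$gain_pps_per_dps, 0.78, tolerance = 1e-9)
  # renormalization rescales gain only, never phase
  f <- c(0.2, 2, 20)
  expect_equal(mapping_frequency_response(build_mapping("mixed"), f)$phase_deg,
               mapping_frequency_response(
                 build_mapping("mixed", renormalize_mixed = TRUE), f)$phase_deg)
})

test_that("dynamic mappings have increasing gain and positive phase lead", {
  f_gain <- seq(0.2, 20, length.out = 40)
  f_phase <- seq(1, 20, length.out = 30)
  for (kind in c("regular", "irregular", "mixed", "super_high_pass")) {
    fr <- mapping_frequency_response(build_mapping(kind), f_gain)
    expect_true(all(diff(fr$gain_pps_per_dps) > 0), label = kind)
    ph <- mapping_frequency_response(build_mapping(kind), f_phase)$phase_deg
    expect_true(all(ph > 0), label = kind)
    expect_true(all(diff(ph) > 0), label = kind)
  }
})

test_that("encoding worked examples hold", {
  # zero head velocity forever -> constant baseline output
  enc0 <- encode_head_velocity(head_series(rep(0, 3000)),
                               build_mapping("regular"))
  expect_equal(enc0$final_rate_pps, rep(150, 3000))

  # static mapping, 50 deg/s 1 Hz sinusoid
  hs <- steady_sinusoid(1, settle_s = 3)
  enc <- encode_head_velocity(hs, build_mapping("static"))
  keep <- hs$time_s >= 3
  expect_equal(max(enc$linear_rate_pps[keep]), 189, tolerance = 1e-3)
  expect_equal(min(enc$linear_rate_pps[keep]), 111, tolerance = 1e-3)
  expect_equal(max(enc$final_rate_pps[keep]), 184.6, tolerance = 1e-3)
  expect_equal(min(enc$final_rate_pps[keep]), 119.4, tolerance = 1e-3)

  # super high-pass x2 at 20 Hz saturates visibly
  hs2 <- steady_sinusoid(20)
  enc2 <- encode_head_velocity(hs2, build_mapping("super_high_pass", 2))
  keep2 <- hs2$time_s >= 20
  expect_equal(max(enc2$linear_rate_pps[keep2]), 732, tolerance = 1e-2)
  expect_equal(max(enc2$final_rate_pps[keep2]), 489, tolerance = 1e-2)

  expect_error(encode_head_velocity(head_series(numeric(0)),
                                    build_mapping("static")), "empty")
})

test_that("linear stage is exactly linear and x2 exactly doubles modulation", {
  hs <- steady_sinusoid(2, settle_s = 1, n_cycles = 4)
  for (kind in c("regular", "mixed", "static")) {
    m1 <- build_mapping(kind)
    m2 <- build_mapping(kind, 2)
    e1 <- encode_head_velocity(hs, m1)
    e2 <- encode_head_velocity(hs, m2)
    mod1 <- e1$linear_rate_pps - 150
    mod2 <- e2$linear_rate_pps - 150
    expect_equal(mod2, 2 * mod1, tolerance = 1e-12, label = kind)
    # scaling the input scales the modulation identically
    hs3 <- hs
    hs3$head_vel_dps <- 3 * hs$head_vel_dps
    e3 <- encode_head_velocity(hs3, m1)
    expect_equal(e3$linear_rate_pps - 150, 3 * mod1, tolerance = 1e-12,
                 label = kind)
  }
})

test_that("discrete-time filtering agrees with the analytic response", {
  # time-domain oracle: steady-state sinusoidal filtering must match the
  # continuous-domain transfer function within 0.5% gain and 0.5 deg phase
  for (kind in c("regular", "irregular", "mixed", "super_high_pass")) {
    m <- build_mapping(kind)
    for (f in c(0.5, 5, 20)) {
      hs <- steady_sinusoid(f)
      enc <- encode_head_velocity(hs, m)
      est <- oracle_sine_fit(enc$linear_rate_pps - 150, hs$time_s, f, 5)
      fr <- mapping_frequency_response(m, f)
      expect_equal(est$amplitude / 50, fr$gain_pps_per_dps,
                   tolerance = 5e-3, label = paste(kind, f, "gain"))
      expect_lt(abs(est$phase_deg - fr$phase_deg), 0.5)
    }
  }
})

test_that("pulse trains are rate-faithful", {
  # constant baseline: 150 pulses per second, uniform intervals
  hs <- head_series(rep(0, 1000))
  pt <- rate_to_pulse_times(encode_head_velocity(hs, build_mapping("static")))
  expect_equal(nrow(pt), 150)
  expect_equal(diff(pt$pulse_time_s), rep(1 / 150, 149), tolerance = 1e-6)
  expect_true(all(diff(pt$pulse_time_s) > 0))

  # modulated rate: reconstructed rate (1/ISI) tracks the commanded rate
  hs <- steady_sinusoid(1, settle_s = 2, n_cycles = 3)
  enc <- encode_head_velocity(hs, build_mapping("static"))
  pt <- rate_to_pulse_times(enc)
  mid <- (pt$pulse_time_s[-1] + pt$pulse_time_s[-nrow(pt)]) / 2
  recon <- 1 / diff(pt$pulse_time_s)
  commanded <- stats::approx(enc$time_s, enc$final_rate_pps, xout = mid)$y
  expect_lt(max(abs(recon / commanded - 1)), 0.05)
})
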