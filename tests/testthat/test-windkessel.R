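test_that("generate_exponential_segment matches the closed form", {
  w <- generate_exponential_segment(60, 100, rc = 1.5, duration = 0.6,
                                    sampling_rate = 1000)
  expect_equal(w$pressure[1], 100)
  expect_equal(w$pressure[w$time == 0.6], 60 + 40 * exp(-0.4),
               tolerance = 1e-12)
  expect_equal(diff(w$time), rep(1e-3, length(w$time) - 1))

  # degenerate zero duration: single sample at p0
  w0 <- generate_exponential_segment(0, 1, rc = 1, duration = 0)
  expect_equal(w0$pressure, 1)
  expect_length(w0$time, 1)
})

test_that("generate_exponential_segment validates its arguments", {
  expect_error(generate_exponential_segment(60, 100, rc = -1, duration = 0.5),
               class = "dpd_invalid_argument")
  expect_error(generate_exponential_segment(60, 100, rc = 1, duration = -1),
               class = "dpd_invalid_argument")
  expect_error(generate_exponential_segment(60, 100, 1, 0.5, sampling_rate = 0),
               class = "dpd_invalid_argument")
  expect_error(generate_exponential_segment(100, 60, 1, 0.5),
               class = "dpd_invalid_argument") # p0 below asymptote
})

test_that("windkessel fixture invariants hold", {
  fx <- windkessel_fixture(resistance = 1.2, compliance = 1.5)
  expect_identical(fx$true_rc, 1.2 * 1.5)
  expect_error(windkessel_fixture(ejection_duration = 1.0, heart_rate = 73),
               class = "dpd_invalid_argument") # ejection >= period
})

test_that("windkessel pulse conserves mean pressure = R x mean inflow", {
  fx <- windkessel_fixture(resistance = 1, compliance = 1.14,
                           peak_inflow = 300, ejection_duration = 0.3,
                           heart_rate = 73)
  w <- generate_windkessel_pulse(fx)
  expect_true(attr(w, "converged"))
  mean_q <- 300 * (2 / pi) * (0.3 / w$period)
  expect_equal(mean(w$pressure), 1 * mean_q, tolerance = 0.005)
})

test_that("fitting the windkessel diastole recovers R*C", {
  # oracle: the homogeneous ODE C dP/dt = -P/R has solution
  # P(t) = P0 exp(-t/RC), so the fitted constant must equal R*C
  fx <- windkessel_fixture(resistance = 1.0, compliance = 1.14)
  w <- generate_windkessel_pulse(fx)
  t_in <- as.numeric(detect_incisura(w))
  for (f in c(1 / 3, 2 / 3, 1)) {
    est <- estimate_rc(w, f, t_in = t_in)
    expect_equal(est$rc, fx$true_rc, tolerance = 0.01)
  }
})

test_that("fitted RC is grid-independent", {
  rcs <- vapply(c(1000, 2000), function(fs) {
    fx <- windkessel_fixture(sampling_rate = fs)
    w <- generate_windkessel_pulse(fx)
    estimate_rc(w, 2 / 3, t_in = as.numeric(detect_incisura(w)))$rc
  }, numeric(1))
  expect_lt(abs(rcs[2] - rcs[1]) / rcs[1], 1e-4)
})

test_that("3-parameter fit recovers true_rc from any admissible seed", {
  fx <- windkessel_fixture(resistance = 1.0, compliance = 1.14)
  w <- generate_windkessel_pulse(fx)
  win <- select_window(w, as.numeric(detect_incisura(w)), 1)
  est <- fit_mono_exponential(win, asymptote = "free")
  expect_equal(est$rc, fx$true_rc, tolerance = 1e-4)
})

test_that("very large compliance shrinks the pulse swing monotonically", {
  swing <- vapply(c(1, 100), function(C) {
    w <- generate_windkessel_pulse(windkessel_fixture(compliance = C))
    diff(range(w$pressure))
  }, numeric(1))
  expect_lt(swing[2], swing[1])
})

test_that("waveform round-trips through the shared text dialect", {
  fx <- windkessel_fixture()
  w <- generate_windkessel_pulse(fx)
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform(w, path)
  w2 <- read_waveform(path, site = "windkessel")
  expect_equal(w2$pressure, w$pressure, tolerance = 1e-12)
  expect_equal(w2$time, w$time, tolerance = 1e-12)
  expect_equal(w2$flow, w$flow, tolerance = 1e-12)
})
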