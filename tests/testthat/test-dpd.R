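test_that("incisura detection follows the flow when available", {
  # constructed half-sine flow ending at 0.35 s with decaying pressure
  t <- seq(0, 0.8, by = 1e-3)
  q <- ifelse(t < 0.35, 200 * sin(pi * t / 0.35), 0)
  p <- 100 * exp(-t / 2) + 20
  w <- pressure_waveform(t, p, flow = q, period = 0.801)
  t_in <- detect_incisura(w)
  # the 1% threshold is crossed one to two samples before the zero itself
  expect_lt(abs(as.numeric(t_in) - 0.35), 2.5e-3)
  expect_identical(attr(t_in, "method"), "flow")

  # fixture ground truth: inflow ends at ejection_duration
  fx <- windkessel_fixture(ejection_duration = 0.3)
  wk <- generate_windkessel_pulse(fx)
  expect_lt(abs(as.numeric(detect_incisura(wk)) - attr(wk, "t_flow_zero")),
            2.5e-3)
})

test_that("incisura detection errors on degenerate input", {
  t <- seq(0, 0.8, by = 1e-3)
  w <- pressure_waveform(t, 120 * exp(-t), period = 0.801)  # no flow, no notch
  expect_error(detect_incisura(w), class = "dpd_detection_error")
})

test_that("notch fallback finds a pressure local minimum after the peak", {
  t <- seq(0, 0.8, by = 1e-3)
  p <- ifelse(t < 0.35, 80 + 35 * sin(pi * t / 0.35),
       ifelse(t < 0.45, 80 - 6 * sin(pi * (t - 0.35) / 0.1),
              80 * exp(-(t - 0.45) / 1.5)))
  w <- pressure_waveform(t, p, period = 0.801)   # notch (local min) at 0.40
  t_in <- detect_incisura(w)
  expect_identical(attr(t_in, "method"), "notch")
  expect_equal(as.numeric(t_in), 0.40, tolerance = 0.02)
})

test_that("window selection implements the backward fractions", {
  t <- seq(0, 0.9, by = 1e-3)
  w <- pressure_waveform(t, 100 * exp(-t), period = 0.901)
  w23 <- select_window(w, 0.3, 2 / 3)
  expect_equal(w23$window_start, 0.5)
  expect_equal(range(w23$time), c(0.5, 0.9))
  expect_equal(select_window(w, 0.3, 1 / 3)$window_start, 0.7)
  expect_equal(select_window(w, 0.3, 1)$window_start, 0.3)
  expect_error(select_window(w, 0.3, 0.5), class = "dpd_invalid_argument")
  # fewer than 10 samples
  ws <- pressure_waveform(seq(0, 0.9, by = 0.1), 100 * exp(-seq(0, 0.9, 0.1)),
                          period = 1)
  expect_error(select_window(ws, 0.85, 1 / 3), class = "dpd_window_error")
})

test_that("the free-asymptote fit recovers exact exponentials to 1e-6", {
  win <- exp_window(p_inf = 60, amp = 40, rc = 1.5)
  est <- fit_mono_exponential(win, asymptote = "free")
  expect_equal(est$rc, 1.5, tolerance = 1e-6)
  expect_equal(est$p_inf, 60, tolerance = 1e-4)
  expect_equal(est$amplitude, 40, tolerance = 1e-4)
  expect_false(est$flagged)
})

test_that("the zero-asymptote fit is exact on venous-referenced decays", {
  win <- exp_window(p_inf = 0, amp = 110, rc = 2.2)
  est <- fit_mono_exponential(win)
  expect_equal(est$rc, 2.2, tolerance = 1e-6)
  expect_identical(est$p_inf, 0)
})

test_that("fit is invariant to time origin and equivariant to scale", {
  win <- exp_window(p_inf = 0, amp = 110, rc = 1.8)
  shifted <- win
  shifted$time <- win$time + 5
  shifted$window_start <- win$window_start + 5
  expect_equal(fit_mono_exponential(shifted)$rc, fit_mono_exponential(win)$rc,
               tolerance = 1e-9)
  scaled <- win
  scaled$pressure <- 3 * win$pressure
  e1 <- fit_mono_exponential(win); e2 <- fit_mono_exponential(scaled)
  expect_equal(e2$rc, e1$rc, tolerance = 1e-9)
  expect_equal(e2$amplitude, 3 * e1$amplitude, tolerance = 1e-6)
})

test_that("window nesting gives identical tau on a pure exponential", {
  w <- generate_exponential_segment(0, 110, rc = 1.3, duration = 0.6)
  taus <- vapply(c(1 / 3, 2 / 3, 1), function(f)
    estimate_rc(w, f, t_in = 0)$rc, numeric(1))
  expect_lt(max(abs(taus - 1.3)) / 1.3, 1e-6)
})

test_that("degenerate fits are flagged, constant windows error", {
  win <- exp_window(p_inf = 0, amp = 110, rc = 1.5)
  win$pressure <- rep(80, length(win$time))
  expect_error(fit_mono_exponential(win), class = "dpd_invalid_argument")
  # a linear rise cannot be fit by a decay: tau runs to a bound -> flagged
  win2 <- exp_window(p_inf = 0, amp = 110, rc = 1.5)
  win2$pressure <- 50 + 100 * win2$time
  est <- fit_mono_exponential(win2)
  expect_true(est$flagged)
})
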