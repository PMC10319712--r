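test_that("normalized elastance peaks at t_maxE and is low at the ends", {
  expect_equal(normalized_elastance(0.340, t_maxE = 0.340), 1.0)
  expect_lt(normalized_elastance(0, t_maxE = 0.340), 0.05)
  expect_lt(normalized_elastance(0.95 * (60 / 60), t_maxE = 0.340,
                                 heart_rate = 60), 0.05)
  expect_error(normalized_elastance(1.2, heart_rate = 73),
               class = "dpd_invalid_argument")
})

test_that("local pwv follows the Bramwell-Hill form", {
  expect_equal(compute_local_pwv(3.6e-5, 1050), 1 / sqrt(1050 * 3.6e-5),
               tolerance = 1e-12)
  expect_equal(round(compute_local_pwv(3.6e-5, 1050), 3), 5.143)
  # D -> 4D halves the speed exactly
  expect_equal(compute_local_pwv(4 * 3.6e-5), compute_local_pwv(3.6e-5) / 2)
  expect_error(compute_local_pwv(-1e-5), class = "dpd_invalid_argument")
})

test_that("characteristic impedance has the right value and scaling", {
  z <- compute_characteristic_impedance(3.0, 5.15, 1050)
  expect_equal(round(z, 4), 0.0574)
  # doubling the area (diameter x sqrt(2)) halves Z exactly
  z2 <- compute_characteristic_impedance(3.0 * sqrt(2), 5.15, 1050)
  expect_equal(z2, z / 2, tolerance = 1e-12)
  expect_error(compute_characteristic_impedance(0, 5),
               class = "dpd_invalid_argument")
})

test_that("pressure summaries extract SBP/DBP/PP/MAP", {
  w <- pressure_waveform(c(0, 0.1, 0.2), c(80, 120, 80), period = 0.3)
  s <- summarize_pressure(w)
  expect_equal(s$sbp, 120)
  expect_equal(s$dbp, 80)
  expect_equal(s$pp, 40)
  wc <- pressure_waveform(seq(0, 0.9, 0.1), rep(90, 10), period = 1)
  sc <- summarize_pressure(wc)
  expect_equal(unlist(sc[c("sbp", "dbp", "map", "pp")]),
               c(sbp = 90, dbp = 90, map = 90, pp = 0))
})

test_that("tree compliance bookkeeping is analytic and exact", {
  tree <- load_arterial_tree()
  c_seg <- sum(segment_compliances(tree))
  expect_equal(tree_total_compliance(tree), c_seg)
  tree2 <- set_vascular_targets(tree, 1.14, 1.0)
  expect_equal(tree_total_compliance(tree2), 1.14, tolerance = 1e-12)
  expect_equal(sum(tree2$terminals$compliance), 0.2 * 1.14, tolerance = 1e-12)
})

test_that("the reference subject obeys steady-state physics", {
  sim <- reference_simulation()
  expect_true(sim$converged)
  # conservation: MAP = TPR x CO within 2% (venous reference 0)
  map <- sim$summaries$aortic_root$map
  expect_equal(map, 1.0 * sim$metrics$cardiac_output_ml_s, tolerance = 0.02)
  # peripheral amplification
  expect_gte(sim$summaries$left_common_carotid$pp, sim$summaries$aortic_root$pp)
  expect_gte(sim$summaries$brachial$pp, sim$summaries$aortic_root$pp)
  # ventricular volume stays above the dead volume
  expect_true(all(sim$v_lv >= 15))
})

test_that("the carotid foot lags the aortic foot consistently with pwv", {
  sim <- reference_simulation()
  lag <- dpdecay:::pulse_foot_time(sim$waveforms$left_common_carotid) -
    dpdecay:::pulse_foot_time(sim$waveforms$aortic_root)
  expect_gt(lag, 0)
  # transit estimate over ascending aorta + arch + left common carotid
  tree <- set_vascular_targets(load_arterial_tree(), 1.14, 1.0)
  seg <- tree$segments
  path <- seg[seg$name %in% c("ascending_aorta", "aortic_arch_a",
                              "left_common_carotid"), ]
  transit <- sum(path$length_cm / 100 /
                   (1 / sqrt(1050 * path$distensibility_per_Pa)))
  expect_lt(abs(lag - transit) / transit, 0.30)
})

test_that("simulation is bit-reproducible", {
  tree <- set_vascular_targets(load_arterial_tree(), 1.14, 1.0)
  s1 <- simulate_subject(cardiac_params(), tree)
  s2 <- simulate_subject(cardiac_params(), tree)
  expect_identical(s1$waveforms$aortic_root$pressure,
                   s2$waveforms$aortic_root$pressure)
  expect_identical(s1$waveforms$left_common_carotid$pressure,
                   s2$waveforms$left_common_carotid$pressure)
})

test_that("halving distensibility shortens the fitted aortic decay", {
  # brute monotonicity check: stiffer tree (smaller C) -> smaller tau
  tree_soft <- set_vascular_targets(load_arterial_tree(), 1.6, 1.0)
  tree_stiff <- set_vascular_targets(load_arterial_tree(), 0.8, 1.0)
  tau <- vapply(list(tree_soft, tree_stiff), function(tr) {
    sim <- simulate_subject(cardiac_params(), tr)
    ao <- sim$waveforms$aortic_root
    ao <- rotate_waveform(ao, ao$time[which.min(ao$pressure)])
    estimate_rc(ao, 2 / 3, t_in = 0.35)$rc
  }, numeric(1))
  expect_lt(tau[2], tau[1])
})
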