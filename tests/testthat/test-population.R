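test_that("sampling is deterministic and respects the ranges", {
  d1 <- sample_parameters(n = 200, seed = 42)
  d2 <- sample_parameters(n = 200, seed = 42)
  expect_identical(d1, d2)
  d3 <- sample_parameters(n = 200, seed = 43)
  expect_false(identical(d1$E_es, d3$E_es))

  big <- sample_parameters(n = 10000, seed = 1)
  r <- parameter_ranges()
  for (nm in names(r$ranged)) {
    expect_gte(min(big[[nm]]), r$ranged[[nm]][1])
    expect_lte(max(big[[nm]]), r$ranged[[nm]][2])
  }
  # Monte-Carlo oracle of the declared truncated-Gaussian law: the
  # truncation at [60, 100] around center 73 shifts the mean up slightly
  # (simulated with rnorm + rejection below)
  set.seed(99)
  x <- rnorm(2e5, 73, 10); x <- x[x >= 60 & x <= 100][1:1e5]
  expect_equal(mean(big$heart_rate), mean(x), tolerance = 0.01)
})

test_that("rejected configuration errors are raised", {
  r <- parameter_ranges()
  r$ranged$E_es <- c(3.5, 1.03)
  expect_error(sample_parameters(r, 10, 1), class = "dpd_config_error")
  expect_error(sample_parameters(n = 0), class = "dpd_invalid_argument")
})

test_that("subject tree scaling hits its targets analytically", {
  ref <- load_arterial_tree()
  draw <- list(inlet_diameter = 3.0, height = 180,
               total_arterial_compliance = 1.14,
               total_peripheral_resistance = 1.0)
  tr <- build_scaled_tree(ref, draw)
  expect_equal(tr$scaling$length_scale, 1)     # height 180 -> identity
  expect_equal(tr$scaling$diameter_scale, 1)   # reference inlet is 3.0 cm
  expect_equal(tree_total_compliance(tr), 1.14, tolerance = 1e-12)

  # doubling sampled C doubles every compliance entry
  tr2 <- build_scaled_tree(ref, modifyList(draw,
                                           list(total_arterial_compliance = 2.28)))
  expect_equal(segment_compliances(tr2), 2 * segment_compliances(tr),
               tolerance = 1e-12)
  expect_equal(tr2$terminals$compliance, 2 * tr$terminals$compliance,
               tolerance = 1e-12)
})

test_that("scaling meets targets within 0.1% over random draws", {
  ref <- load_arterial_tree()
  set.seed(5)
  for (k in 1:100) {
    draw <- list(inlet_diameter = runif(1, 1.9, 4),
                 height = runif(1, 150, 200),
                 total_arterial_compliance = runif(1, 0.1, 3.8),
                 total_peripheral_resistance = runif(1, 0.5, 2))
    tr <- build_scaled_tree(ref, draw)
    expect_equal(tree_total_compliance(tr), draw$total_arterial_compliance,
                 tolerance = 1e-3)
  }
})

test_that("scaling then un-scaling restores the reference tree", {
  ref <- load_arterial_tree()
  draw <- list(inlet_diameter = 3.6, height = 165,
               total_arterial_compliance = 2.0,
               total_peripheral_resistance = 1.4)
  tr <- build_scaled_tree(ref, draw)
  back <- tr
  back$segments$prox_diam_cm <- back$segments$prox_diam_cm / tr$scaling$diameter_scale
  back$segments$dist_diam_cm <- back$segments$dist_diam_cm / tr$scaling$diameter_scale
  back$segments$length_cm <- back$segments$length_cm / tr$scaling$length_scale
  for (col in c("prox_diam_cm", "dist_diam_cm", "length_cm"))
    expect_equal(back$segments[[col]], ref$segments[[col]], tolerance = 1e-10)
})

test_that("the physiology filter implements mean +/- z SD severally", {
  cfg <- filter_config(z_threshold = 2.807)
  cfg$normotensive[] <- NA
  cfg$normotensive["brachial_sbp", ] <- c(130, 15)
  for (v in rownames(cfg$normotensive)[-1])
    cfg$normotensive[v, ] <- c(100, 1e6)     # effectively unconstrained
  cfg$hypertensive <- cfg$normotensive       # single effective set
  base <- as.list(setNames(rep(100, 8), rownames(cfg$normotensive)))

  mk <- function(sbp) as.data.frame(modifyList(base, list(brachial_sbp = sbp)))
  # acceptance interval is [130 - 2.807*15, 130 + 2.807*15] = [87.9, 172.1]
  v1 <- apply_physiology_filter(mk(175), cfg)
  expect_false(v1$accepted)
  expect_identical(v1$reason, "brachial_sbp")
  expect_true(apply_physiology_filter(mk(130), cfg)$accepted)
  expect_true(apply_physiology_filter(mk(87.95), cfg)$accepted)
  expect_false(apply_physiology_filter(mk(87.80), cfg)$accepted)
})

test_that("the filter is idempotent and order-independent", {
  set.seed(3)
  df <- as.data.frame(matrix(rnorm(8 * 50, 100, 40), 50, 8))
  names(df) <- rownames(filter_config()$normotensive)
  v1 <- apply_physiology_filter(df, filter_config())
  v2 <- apply_physiology_filter(df, filter_config())
  expect_identical(v1, v2)
  perm <- sample(50)
  v3 <- apply_physiology_filter(df[perm, ], filter_config())
  expect_identical(v3$accepted, v1$accepted[perm])
})

test_that("missing filter variables raise a configuration error", {
  df <- data.frame(brachial_sbp = 120)
  expect_error(apply_physiology_filter(df, filter_config()),
               class = "dpd_config_error")
})
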