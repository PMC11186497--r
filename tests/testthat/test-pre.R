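test_that("two-time-point PRE follows the log-ratio formula with clamping", {
  expect_equal(pre_two_point(0.7, 0.7, 0, 10e-3)$gamma2, 0)
  r <- pre_two_point(0.45, 0.75, 0, 10e-3)
  expect_equal(r$gamma2, 100 * log(75 / 45))   # = 100 ln(5/3) ~ 51.08
  expect_equal(r$status, "quantified")
  # apparent ratio above the diamagnetic one: clamp to zero, flag no_pre
  r2 <- pre_two_point(0.80, 0.75, 0, 10e-3)
  expect_equal(r2$gamma2, 0)
  expect_equal(r2$status, "no_pre")
  r3 <- pre_two_point(-0.1, 0.75, 0, 10e-3)
  expect_true(is.na(r3$gamma2) && r3$status == "bleached")
})

test_that("volume-ratio PRE uses the total transverse delay", {
  expect_equal(pre_volume_ratio(500, 500, 10.3e-3)$gamma2, 0)
  expect_equal(pre_volume_ratio(0.70, 1, 10.3e-3)$gamma2, -log(0.7) / 10.3e-3)
  expect_equal(pre_volume_ratio(exp(-1), 1, 10.3e-3)$gamma2, 1 / 0.0103)
  expect_equal(pre_volume_ratio(0, 1, 10.3e-3)$status, "bleached")
})

test_that("two-point and volume protocols agree on log-equivalent inputs", {
  # same net log-attenuation over the same effective time
  g1 <- pre_two_point(0.5 * 0.9, 0.9, 0, 12e-3)$gamma2
  g2 <- pre_volume_ratio(0.5, 1, 12e-3)$gamma2
  expect_equal(g1, g2)
})

test_that("the peak-height forward model is 1 at zero PRE and strictly decreasing", {
  s <- default_settings()
  expect_identical(forward_height_ratio(0, s), 1)
  expect_equal(forward_height_ratio(40, s), 0.3047, tolerance = 1e-4)
  grid <- forward_height_ratio(seq(0, 500, by = 2.5), s)
  expect_true(all(diff(grid) < 0))
  expect_true(all(grid > 0 & grid <= 1))
})

test_that("height-ratio inversion is a faithful round trip", {
  s <- default_settings()
  expect_equal(invert_height_ratio(1, s)$gamma2, 0)
  g <- c(0.1, 1, 5, 40, 120, 500)
  back <- invert_height_ratio(forward_height_ratio(g, s), s)
  expect_true(all(abs(back$gamma2 - g) / g < 1e-6))
  expect_equal(invert_height_ratio(0.3047051, s)$gamma2, 40, tolerance = 1e-4)
  # noise pushing the ratio above 1 clamps; vanished peaks are bleached
  up <- invert_height_ratio(1.05, s)
  expect_equal(up$gamma2, 0); expect_equal(up$status, "no_pre")
  expect_equal(invert_height_ratio(0, s)$status, "bleached")
})

test_that("inversion round trip holds across randomized acquisition settings", {
  set.seed(11)
  for (k in 1:25) {
    s <- acquisition_settings(field_mhz = 850,
                              delta_total = runif(1, 5e-3, 15e-3),
                              lb_f1 = runif(1, 0, 30), lb_f2 = runif(1, 0, 30),
                              r2_dia_h = runif(1, 5, 60),
                              r2_dia_mq = runif(1, 5, 80))
    g <- exp(runif(4, log(0.1), log(500)))
    back <- invert_height_ratio(forward_height_ratio(g, s), s)$gamma2
    expect_true(all(abs(back - g) / g < 1e-6))
  }
})

test_that("extracted PRE is invariant to a common intensity scale", {
  s <- default_settings()
  r0 <- invert_height_ratio(100 / 400, s)$gamma2
  r1 <- invert_height_ratio((100 * 7.3) / (400 * 7.3), s)$gamma2
  expect_equal(r0, r1)
})

test_that("exponential decay fitting recovers rates", {
  d <- c(0, 2, 5, 10, 15, 20, 30, 40) / 1e3
  # noiseless: exact recovery
  f <- fit_exponential_decay(d, 1000 * exp(-50 * d))
  expect_equal(f$rate, 50, tolerance = 1e-8)
  expect_equal(f$i0, 1000, tolerance = 1e-6)
  # two points: closed form -ln(ratio)/dt
  f2 <- fit_exponential_decay(c(0, 10e-3), c(1000, 1000 * exp(-0.5)))
  expect_equal(f2$rate, 50)
  # noisy simulation: mean over seeds close to truth
  rates <- vapply(1:60, function(s) {
    tab <- simulate_decay_series(50, d, noise_sigma = 0.02, seed = s)
    fit_exponential_decay(tab$delay, tab$intensity)$rate
  }, numeric(1))
  expect_lt(abs(mean(rates) - 50) / 50, 0.02)
  expect_error(fit_exponential_decay(c(1e-3, 1e-3), c(10, 10)), "singular")
})

test_that("split peaks combine by summation before forming the ratio", {
  expect_equal(merge_split_peaks(10), 10)
  expect_equal(merge_split_peaks(c(6, 4)), 10)
  expect_equal(merge_split_peaks(c(3, 2)) / merge_split_peaks(c(6, 4)), 0.5)
})

test_that("Monte Carlo PRE uncertainty is seeded and scales with input error", {
  s <- default_settings()
  zero <- monte_carlo_pre_uncertainty(300, 1000, s, errors = list(),
                                      n_reps = 100, seed = 7)
  expect_identical(as.numeric(zero), 0)
  a <- monte_carlo_pre_uncertainty(300, 1000, s,
                                   errors = list(i_para = 15, i_dia = 50),
                                   n_reps = 300, seed = 42)
  b <- monte_carlo_pre_uncertainty(300, 1000, s,
                                   errors = list(i_para = 15, i_dia = 50),
                                   n_reps = 300, seed = 42)
  expect_identical(a, b)
  expect_gt(as.numeric(a), 0)
})

test_that("Monte Carlo uncertainty agrees with a larger-replicate estimate", {
  s <- default_settings()
  err <- list(i_para = 0.05 * 300, i_dia = 0.05 * 1000)
  small <- as.numeric(monte_carlo_pre_uncertainty(300, 1000, s, err,
                                                  n_reps = 2000, seed = 3))
  big <- as.numeric(monte_carlo_pre_uncertainty(300, 1000, s, err,
                                                n_reps = 20000, seed = 99))
  expect_lt(abs(small - big) / big, 0.15)
})

test_that("peak tables are validated and drive the extraction modes", {
  s <- default_settings()
  tab <- data.frame(tag_site = "B10C", chain = "A", resnum = 1:3,
                    probe = "N", i_para = c(300, 500, 0),
                    i_dia = c(1000, 1000, 1000),
                    v_para = NA, v_dia = NA, sigma_i = NA)
  p <- tempfile(fileext = ".tsv")
  utils::write.table(tab, p, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_peak_table(p)
  expect_equal(back$i_para, tab$i_para)
  ex <- extract_pre(back, s, mode = "height")
  expect_equal(ex$status, c("quantified", "quantified", "bleached"))
  expect_equal(forward_height_ratio(ex$gamma2[1], s), 0.3, tolerance = 1e-9)
  bad <- tab; bad$i_para <- NULL
  p2 <- tempfile(fileext = ".tsv")
  utils::write.table(bad, p2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_peak_table(p2), "i_para")
})
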