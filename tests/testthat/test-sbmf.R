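test_that("kappa_H reproduces the standard PRE prefactor", {
  k <- kappa_h()
  expect_equal(signif(k, 5), 1.2311e16)
  expect_equal(signif(kappa_h(si = TRUE), 5), 1.2311e-44)
  # substituting gamma_C scales by (gamma_C/gamma_H)^2
  co <- physical_constants()
  co_c <- physical_constants(gamma_h = co$gamma_c)
  expect_equal(kappa_h(co_c) / k, (co$gamma_c / co$gamma_h)^2)
  expect_equal((co$gamma_c / co$gamma_h)^2, 0.0633, tolerance = 1e-3)
  # the CODATA free-electron g-factor is available as an override
  expect_gt(kappa_h(physical_constants(g_e = codata_electron_g())), k)
})

test_that("the multiple-quantum PRE factor evaluates from gyromagnetic ratios", {
  expect_equal(round(mq_pre_factor(), 3), 1.063)
})

test_that("the model-free spectral density has the closed-form limits", {
  p <- sbmf_parameters(tau_1 = 20e-9, tau_i = 1e-9, s2 = 0.8)
  expect_equal(p$tau_t, 1 / (1 / 20e-9 + 1 / 1e-9))
  expect_equal(j_sbmf(0, p), 0.8 * 20e-9 + 0.2 * p$tau_t)
  expect_equal(j_sbmf(0, p), 1.619e-8, tolerance = 1e-3)
  # S^2 = 1: single Lorentzian
  p1 <- sbmf_parameters(tau_1 = 20e-9, s2 = 1)
  w <- 5e9
  expect_equal(j_sbmf(w, p1), 20e-9 / (1 + w^2 * (20e-9)^2))
  # J(0) bounds J(omega) everywhere
  ws <- 10^seq(6, 11, length.out = 40)
  expect_true(all(j_sbmf(ws, p) <= j_sbmf(0, p)))
})

test_that("Gamma2 from distance follows the simplified Solomon-Bloembergen form", {
  p <- sbmf_parameters(tau_1 = 20e-9, s2 = 1, field_mhz = 850)
  g20 <- gamma2_from_distance(20, p)
  expect_equal(g20, 15.39, tolerance = 1e-3)
  # r^-6 scaling: halving r multiplies by 64
  expect_equal(gamma2_from_distance(10, p) / g20, 64)
  # omega -> 0 limit gives the 4+3 factor
  p0 <- sbmf_parameters(tau_1 = 20e-9, s2 = 1, field_mhz = 1e-6)
  expect_equal(gamma2_from_distance(20, p0),
               kappa_h() / 20^6 * 20e-9 * 7, tolerance = 1e-6)
  # full two-term form reduces to the simplified one when S^2 = 1
  expect_equal(gamma2_from_distance(20, p, full = TRUE), g20)
})

test_that("distance/Gamma2 conversion is a monotone exact inverse pair", {
  p <- sbmf_parameters()
  expect_equal(distance_from_gamma2(gamma2_from_distance(20, p), p), 20,
               tolerance = 1e-9)
  r <- c(12, 18, 25, 33)
  expect_equal(distance_from_gamma2(gamma2_from_distance(r, p), p), r,
               tolerance = 1e-9)
  # Gamma2 x 64 halves the distance; smaller Gamma2 -> larger distance
  g <- gamma2_from_distance(20, p)
  expect_equal(distance_from_gamma2(64 * g, p), 10, tolerance = 1e-9)
  expect_true(all(diff(distance_from_gamma2(c(1, 5, 20, 80), p)) < 0))
  expect_error(distance_from_gamma2(0, p), "non-positive")
})

test_that("back-calculation averages r^-6 over the tag conformer ensemble", {
  m <- tiny_model(rbind(c(0, 0, 0), c(1.5, 0, 0)), resno = c(1, 1),
                  atom = c("CA", "CB"))
  probes <- data.frame(chain = "A", resno = 1, atom = "CA")
  p <- sbmf_parameters()
  # ensemble of one: identical to the plain distance conversion
  t1 <- tag_site("x", atom_sel("A", 1, "CB"), matrix(c(15, 0, 0), ncol = 3))
  b1 <- back_calculate_pre_profile(m, t1, probes, p)
  expect_equal(b1$gamma2, gamma2_from_distance(15, p))
  # two conformers at 15 and 25 A: Gamma2 proportional to mean of r^-6
  t2 <- tag_site("x", atom_sel("A", 1, "CB"),
                 rbind(c(15, 0, 0), c(25, 0, 0)))
  b2 <- back_calculate_pre_profile(m, t2, probes, p)
  expect_equal(b2$gamma2 / b1$gamma2, (15^-6 + 25^-6) / 2 / 15^-6)
  # a remote conformer (>60 A) is negligible next to close ones
  t3 <- tag_site("x", atom_sel("A", 1, "CB"),
                 rbind(c(15, 0, 0), c(80, 0, 0)))
  g3 <- back_calculate_pre_profile(m, t3, probes, p)$gamma2
  expect_lt(abs(g3 - b1$gamma2 / 2) / (b1$gamma2 / 2), 0.02)
  # unresolved probes are reported, not fatal
  pr2 <- rbind(probes, data.frame(chain = "A", resno = 99, atom = "CA"))
  b4 <- back_calculate_pre_profile(m, t1, pr2, p)
  expect_equal(nrow(b4), 1)
  expect_equal(attr(b4, "unresolved")$resno, 99)
})

test_that("correlation-time fitting recovers the generating tau_1", {
  tr <- make_toy_complex(n_residues_a = 25, seed = 8)
  site <- names(tr$tag_sites)[1]
  meas <- data.frame(chain = "A", resno = tr$probes$resno, atom = "N",
                     gamma2 = tr$true_gamma2[[site]], status = "quantified")
  fit <- fit_correlation_time(meas, tr$complex_model, tr$tag_sites[[site]],
                              tr$params, n_boot = 0)
  expect_lt(abs(fit$tau_1 - 20e-9), 0.1e-9)
  expect_gte(fit$tau_1, 5e-9); expect_lte(fit$tau_1, 40e-9)
  # with noise, the bootstrap uncertainty is positive and seeded
  set.seed(1)
  meas$gamma2 <- meas$gamma2 * (1 + 0.1 * rnorm(nrow(meas)))
  f1 <- fit_correlation_time(meas, tr$complex_model, tr$tag_sites[[site]],
                             tr$params, n_boot = 50, seed = 5)
  f2 <- fit_correlation_time(meas, tr$complex_model, tr$tag_sites[[site]],
                             tr$params, n_boot = 50, seed = 5)
  expect_identical(f1, f2)
  expect_gt(f1$tau_1_se, 0)
  expect_error(fit_correlation_time(meas[1:3, ], tr$complex_model,
                                    tr$tag_sites[[site]], tr$params),
               "at least 5")
})
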