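test_that("stomatal conductance converts to the CO2 basis by 1.6", {
  expect_equal(stomatal_conductance_co2(0.16), 0.10)
  expect_equal(stomatal_conductance_co2(1.6), 1.0)
  # LVPD regression evaluated at 0.5 kPa then converted
  gsw <- predict_linear(ref_vpd_trends("LVPD")$gs, 0.5)
  expect_equal(gsw, 0.828)
  expect_equal(stomatal_conductance_co2(gsw), 0.5175)
  expect_error(stomatal_conductance_co2(0), "positive")
})

test_that("fluorescence electron transport rate follows its definition", {
  expect_equal(electron_transport_rate(0, 1100), 0)
  expect_equal(electron_transport_rate(0.5, 1100), 231.0)
  expect_error(electron_transport_rate(1.2, 1100), "phi_psii")
  expect_error(electron_transport_rate(0.5, -5), "ppfd")
})

test_that("variable-J gm equals the closed form and the bisection oracle", {
  gm <- variable_j_gm(pn = 20, ci = 300, j = 150, rd = 1, gamma_star = 40)
  expect_equal(gm, 20 / (300 - 40 * (150 + 8 * 21) / (150 - 4 * 21)),
               tolerance = 1e-12)
  expect_equal(gm, oracle_variable_j_gm(20, 300, 150, 1, 40),
               tolerance = 1e-6)
  expect_equal(gm, 0.186441, tolerance = 1e-5)
})

test_that("variable-J gm recovers the generator gm on noiseless records", {
  p <- default_params()
  d <- simulate_vpd_response(p, vpd_response_params("LVPD"), noise = FALSE)
  one <- d[d$rep == 1, ]
  j <- electron_transport_rate(one$phi_psii, one$ppfd)
  gm_hat <- variable_j_gm(one$pn, one$ci_umol_mol, j, p$rd, p$gamma_star)
  expect_equal(gm_hat, one$gm_true, tolerance = 1e-8)
})

test_that("variable-J gm rejects or flags inconsistent inputs", {
  expect_error(variable_j_gm(20, 300, 80, 1, 40), "inconsistent")
  expect_error(variable_j_gm(-1, 300, 150, 1, 40), "pn > 0")
  # Ci below the implied Cc: flagged NA, not an exception
  expect_warning(out <- variable_j_gm(20, 150, 150, 1, 40), "flagged")
  expect_true(is.na(out))
  # zero-flux limit with rd = 0: gm -> pn / (ci - gamma_star) -> 0
  expect_lt(variable_j_gm(1e-8, 300, 150, 0, 40), 1e-7)
})

test_that("variable-J gm is monotone decreasing in Ci where defined", {
  # at fixed (pn, j, rd, gamma_star) the implied Cc is fixed, so a larger Ci
  # means a larger mesophyll draw-down and a smaller conductance estimate
  ci <- seq(260, 360, by = 10)
  gm <- variable_j_gm(rep(20, length(ci)), ci, 150, 1, 40)
  expect_true(all(diff(gm) < 0))
})

test_that("series total conductance has harmonic-mean structure", {
  expect_equal(total_conductance(0.4, 0.4), 0.2)
  expect_equal(total_conductance(0.25, 0.30), 1 / (1 / 0.25 + 1 / 0.30))
  expect_equal(total_conductance(0.25, 1e9), 0.25, tolerance = 1e-8)
  g <- c(0.05, 0.2, 0.7, 1.3)
  expect_equal(total_conductance(g, g), g / 2)
  expect_equal(total_conductance(0.13, 0.57), total_conductance(0.57, 0.13))
  expect_true(all(total_conductance(0.3, g) <= pmin(0.3, g)))
  expect_error(total_conductance(0, 0.3), "positive")
})

test_that("chloroplastic CO2 and transport ratios follow Fick plumbing", {
  expect_equal(chloroplast_co2(0, 310, 0.2), 310)
  expect_equal(chloroplast_co2(20, 300, 0.1864), 300 - 20 / 0.1864)
  expect_equal(chloroplast_co2(-1, 400, 0.2), 405)  # respiration efflux
  r <- transport_ratios(400, 350, 280)
  expect_equal(unlist(r), c(ci_over_ca = 0.875, cc_over_ca = 0.70,
                            cc_over_ci = 0.80))
  expect_equal(transport_ratios(400, 400, 400),
               data.frame(ci_over_ca = 1, cc_over_ca = 1, cc_over_ci = 1))
  with(transport_ratios(413, 327, 211),
       expect_lt(abs(ci_over_ca * cc_over_ci - cc_over_ca), 1e-12))
})

test_that("derive_conductances appends flagged derived columns", {
  p <- default_params()
  d <- simulate_vpd_response(p, vpd_response_params("HVPD"), noise = FALSE)
  out <- suppressMessages(derive_conductances(d, rd = p$rd,
                                              gamma_star = p$gamma_star))
  expect_true(all(c("gsc", "j", "gm", "gtot", "cc_umol_mol", "gm_valid")
                  %in% names(out)))
  ok <- out$gm_valid
  expect_true(all(ok))  # noiseless records all valid
  expect_equal(out$gm, out$gm_true, tolerance = 1e-8)
  expect_true(all(out$gtot[ok] <= pmin(out$gsc[ok], out$gm[ok]) + 1e-12))
  expect_equal(1 / out$gtot, 1 / out$gsc + 1 / out$gm, tolerance = 1e-9)
  # Rubisco screening drops the high-VPD points when requested
  scr <- suppressMessages(derive_conductances(d, rd = p$rd,
                                              gamma_star = p$gamma_star,
                                              screen_rubisco = TRUE))
  expect_true(all(!scr$gm_valid[scr$limitation == "rubisco"]))
})

test_that("replicate-mean gm inversion matches per-record gm when noiseless", {
  p <- default_params()
  d <- simulate_vpd_response(p, vpd_response_params("LVPD"),
                             vpd_grid = 1.5, noise = FALSE)
  gm_hat <- gm_from_replicates(d, rd = p$rd, gamma_star = p$gamma_star)
  expect_equal(gm_hat, d$gm_true[1], tolerance = 1e-8)
  expect_true(is.na(gm_from_replicates(d[0, ], 1, 40)))
})
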