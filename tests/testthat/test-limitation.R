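test_that("dA/dCc slope works on its window and ignores points outside", {
  curve <- data.frame(cc_umol_mol = c(45, 60, 80, 100),
                      pn = 0.12 * c(45, 60, 80, 100) - 4)
  expect_equal(da_dcc_slope(curve), 0.12, tolerance = 1e-12)
  with_far <- rbind(curve, data.frame(cc_umol_mol = 300, pn = 55))
  expect_equal(da_dcc_slope(with_far), 0.12, tolerance = 1e-12)
  expect_error(da_dcc_slope(curve[1:2, ]), "\\[40, 110\\]")
})

test_that("dA/dCc slope tracks the analytic Rubisco derivative", {
  p <- default_params()
  ramp <- generate_aci_curve(p, 0.25, 0.3, std_env(),
                             ca_protocol = c(50, 75, 100, 125, 150))
  ramp$cc_umol_mol <- ramp$cc_true
  k <- da_dcc_slope(ramp)
  inwin <- ramp$cc_true >= 40 & ramp$cc_true <= 110
  expect_gte(sum(inwin), 3)
  expected <- analytic_dac_dcc(mean(range(ramp$cc_true[inwin])), p)
  expect_lt(abs(k / expected - 1), 0.05)
})

test_that("partition reproduces the symmetric worked case and its limits", {
  pt <- partition(gsc = 0.2, gm = 0.2, da_dcc = 0.1)
  expect_equal(c(pt$ls, pt$lm, pt$lb), c(0.25, 0.25, 0.50), tolerance = 1e-12)
  # diffusion-only limit: k -> Inf kills the biochemical fraction and splits
  # the rest in proportion to the resistances
  big <- partition(gsc = 0.25, gm = 0.30, da_dcc = 1e9)
  expect_lt(big$lb, 1e-8)
  expect_equal(big$ls / big$lm, 0.30 / 0.25, tolerance = 1e-6)
  expect_error(partition(-0.1, 0.3, 0.1), "gsc")
  expect_error(partition(0.1, 0.3, 0), "da_dcc")
})

test_that("fractions sum to one and respond monotonically as they must", {
  set.seed(101)
  gsc <- stats::runif(300, 0.01, 2)
  gm <- stats::runif(300, 0.01, 2)
  k <- stats::runif(300, 0.01, 2)
  pt <- partition(gsc, gm, k)
  expect_true(all(abs(pt$ls + pt$lm + pt$lb - 1) < 1e-9))
  expect_true(all(pt$ls >= 0 & pt$ls <= 1 & pt$lm >= 0 & pt$lm <= 1 &
                    pt$lb >= 0 & pt$lb <= 1))
  # swapping gsc and gm swaps Ls and Lm and leaves Lb unchanged
  sw <- partition(gm, gsc, k)
  expect_equal(sw$ls, pt$lm, tolerance = 1e-12)
  expect_equal(sw$lm, pt$ls, tolerance = 1e-12)
  expect_equal(sw$lb, pt$lb, tolerance = 1e-12)
  # finite-difference directions: Ls decreasing in gsc, Lb increasing in 1/k
  base <- partition(0.3, 0.4, 0.15)
  expect_lt(partition(0.3 * 1.01, 0.4, 0.15)$ls, base$ls)
  expect_gt(partition(0.3, 0.4, 0.15 / 1.01)$lb, base$lb)
})

test_that("partition profile shows rising diffusive and falling biochemical shares", {
  p <- default_params()
  resp <- vpd_response_params("LVPD")
  vpd <- c(0.5, 1.5, 2.5, 3.5)
  gsw <- resp$gs_slope * vpd + resp$gs_intercept
  gmv <- resp$gm_slope * vpd + resp$gm_intercept
  k <- vapply(vpd, function(v) {
    ramp <- generate_aci_curve(p, stomatal_conductance_co2(gsw[which(vpd == v)]),
                               gmv[which(vpd == v)],
                               std_env(vpd = v),
                               ca_protocol = c(50, 75, 100, 125, 150))
    ramp$cc_umol_mol <- ramp$cc_true
    da_dcc_slope(ramp)
  }, numeric(1))
  prof <- partition_profile(data.frame(
    vpd = vpd, gsc = stomatal_conductance_co2(gsw), gm = gmv, da_dcc = k,
    regime = "LVPD", cultivar = "CV1"))
  expect_true(all(abs(prof$partitions$ls + prof$partitions$lm +
                        prof$partitions$lb - 1) < 1e-9))
  tr <- prof$trends
  expect_gt(tr$slope[tr$fraction == "ls"], 0)
  expect_lt(tr$slope[tr$fraction == "lb"], 0)
  # stomata close faster than biochemistry declines, so Ls rises level to level
  expect_true(all(diff(prof$partitions$ls) > 0))
})
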