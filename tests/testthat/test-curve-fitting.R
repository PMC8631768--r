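test_that("carboxylation efficiency is the low-CO2 Pn-Ci slope", {
  curve <- data.frame(ca_umol_mol = c(50, 100, 150, 200),
                      ci_umol_mol = c(45, 90, 140, 190))
  curve$pn <- 0.08 * curve$ci_umol_mol - 3
  fit <- fit_ce(curve)
  expect_equal(fit$ce, 0.08, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # slope invariant under record reordering
  fit2 <- fit_ce(curve[c(3, 1, 4, 2), ])
  expect_equal(fit2$ce, fit$ce)
  # filter contract: points above the Ca cutoff refuse the fit
  high <- curve
  high$ca_umol_mol <- high$ca_umol_mol + 300
  expect_error(fit_ce(high), ">= 3 records")
})

test_that("CE approximates the analytic Rubisco-limited dA/dCi", {
  # near-infinite conductances make Ci ~ Cc, so the initial slope should
  # track dAc/dCc at the low-CO2 points within linearisation error
  p <- default_params()
  cu <- generate_aci_curve(p, 1e3, 1e6, std_env())
  fit <- fit_ce(cu)
  lowca <- cu$ca_umol_mol <= 200
  expected <- analytic_dac_dcc(mean(cu$cc_true[lowca]), p)
  expect_lt(abs(fit$ce / expected - 1), 0.05)
})

test_that("FvCB capacity fit recovers generator truth on a 3x3 grid", {
  for (vcmax in c(90, 110, 130)) {
    for (jmax in c(120, 140, 160)) {
      p <- leaf_phys_params(vcmax = vcmax, jmax = jmax)
      cu <- generate_aci_curve(p, 0.25, 0.3, std_env())
      cu$cc_umol_mol <- cu$cc_true
      fv <- fit_fvcb(cu, rd = p$rd, gamma_star = p$gamma_star)
      expect_true(fv$converged)
      expect_lt(abs(fv$vcmax / vcmax - 1), 0.005)
      expect_lt(abs(fv$jmax / jmax - 1), 0.005)
      expect_equal(fv$axis, "cc")
    }
  }
})

test_that("capacity fit flags an all-Rubisco curve as Jmax-unidentifiable", {
  p <- default_params()
  cu <- generate_aci_curve(p, 0.25, 0.3, std_env(),
                           ca_protocol = c(50, 100, 150, 200, 250, 300))
  cu$cc_umol_mol <- cu$cc_true
  expect_true(all(cu$cc_true < 250))
  fv <- suppressWarnings(fit_fvcb(cu, rd = p$rd, gamma_star = p$gamma_star))
  expect_false(fv$jmax_identifiable)
})

test_that("capacity fit falls back to the Ci axis without a Cc column", {
  p <- default_params()
  cu <- generate_aci_curve(p, 1e3, 1e6, std_env())  # Ci ~ Cc here
  fv <- fit_fvcb(cu[, setdiff(names(cu), "cc_true")],
                 rd = p$rd, gamma_star = p$gamma_star)
  expect_equal(fv$axis, "ci")
  expect_lt(abs(fv$vcmax / p$vcmax - 1), 0.01)
})

test_that("Laisk intersection solves constructed lines exactly", {
  mk <- function(a, b, ci) data.frame(ci_umol_mol = ci, pn = a * ci + b)
  ci <- c(30, 60, 90, 120)
  lo <- mk(0.04, -2.6, ci)
  hi <- mk(0.10, -5.0, ci)
  est <- laisk_intersection(lo, hi)
  expect_equal(est$gamma_star, 40, tolerance = 1e-10)
  expect_equal(est$rd, 1.0, tolerance = 1e-10)
  expect_error(laisk_intersection(lo, lo), "parallel")
  expect_error(laisk_intersection(lo[1:2, ], hi), ">= 3 points")
})

test_that("Laisk procedure is deterministic and seed-free", {
  p <- default_params()
  d <- generate_laisk_dataset(p, 0.25, 10, std_env())
  lo <- d[d$light_level == 75, ]
  hi <- d[d$light_level == 500, ]
  expect_identical(laisk_intersection(lo, hi), laisk_intersection(lo, hi))
})
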