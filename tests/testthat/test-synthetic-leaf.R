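test_that("steady-state solver reaches the infinite-supply and dark limits", {
  p <- example_params()
  e <- std_env()
  r <- solve_steady_state(p, gsc = 1e6, gm = 1e6, e)
  expect_lt(abs(r$cc_true - e$ca), 0.1)

  dark <- solve_steady_state(p, 0.25, 0.3, std_env(ppfd = 0))
  expect_equal(dark$pn, -p$rd, tolerance = 1e-10)
  expect_gt(dark$cc_true, dark$ca_umol_mol)
  expect_equal(dark$j_flu, 0)
})

test_that("steady state matches the bisection oracle fixture", {
  # frozen from the independent bisection oracle (|supply - demand| < 1e-9)
  p <- example_params()
  r <- solve_steady_state(p, 0.25, 0.3, std_env())
  expect_equal(r$cc_true, 269.678405, tolerance = 1e-6)
  expect_equal(r$pn, 17.771127, tolerance = 1e-6)
  expect_equal(r$ci_umol_mol, 328.915493, tolerance = 1e-6)
})

test_that("supply-demand residual vanishes and CO2 cascade is ordered", {
  p <- default_params()
  cases <- expand.grid(gsc = c(0.05, 0.25, 0.6), gm = c(0.1, 0.3, 0.8),
                       ca = c(200, 400, 800))
  for (i in seq_len(nrow(cases))) {
    e <- std_env(ca = cases$ca[i])
    r <- solve_steady_state(p, cases$gsc[i], cases$gm[i], e)
    gtot <- total_conductance(cases$gsc[i], cases$gm[i])
    demand <- fvcb_rates(r$cc_true, p, ppfd = e$ppfd)$a_net
    expect_lt(abs(gtot * (e$ca - r$cc_true) - demand), 1e-6)
    if (r$pn > 0) {
      expect_true(e$ca >= r$ci_umol_mol && r$ci_umol_mol >= r$cc_true)
    } else {
      expect_true(e$ca <= r$ci_umol_mol && r$ci_umol_mol <= r$cc_true)
    }
  }
})

test_that("A-Ci protocol emits the documented record sequence", {
  p <- default_params()
  cu <- generate_aci_curve(p, 0.25, 0.3, std_env())
  expect_equal(nrow(cu), 11L)  # 6 descending + repeated 400 + 4 ascending
  at400 <- cu[cu$ca_umol_mol == 400, ]
  expect_equal(at400$pn[1], at400$pn[2])  # noiseless repeats identical
  asc <- cu[cu$step >= 7, ]
  expect_true(all(diff(asc$pn) >= 0))     # FvCB monotone in supply
})

test_that("two-light low-CO2 dataset behaves as a Laisk protocol should", {
  p <- default_params()
  d <- generate_laisk_dataset(p, 0.25, 10, std_env())
  expect_equal(nrow(d), 8L)
  lo <- d[d$light_level == 75, ]
  hi <- d[d$light_level == 500, ]
  # above the compensation point more light means more assimilation; below
  # it the extra electron flux feeds photorespiration and the curves cross
  expect_gt(hi$pn[hi$ca_umol_mol == 120], lo$pn[lo$ca_umol_mol == 120])
  # both curves pass exactly through (Gamma* - Rd/gm, -Rd): fitted lines
  # must agree there to within line-approximation error
  est <- laisk_intersection(lo, hi)
  expect_lt(abs(est$gamma_star - (40 - 1 / 10)), 3)
  expect_lt(abs(est$rd - 1), 0.3)
})

test_that("VPD-response simulation honours its response functions and seed", {
  p <- default_params()
  resp <- vpd_response_params("LVPD")
  d <- simulate_vpd_response(p, resp, noise = FALSE)
  one <- d[d$rep == 1, ]
  # ABA intercept: scale * exp(0) at VPD 0
  expect_equal(resp$aba_scale * exp(resp$aba_rate * 0), 301.3)
  expect_equal(one$aba_ng_g,
               301.3 * exp(0.15 * one$vpd_kpa), tolerance = 1e-12)
  # noiseless gsw round trip through the regression module
  fit <- fit_response(one$vpd_kpa, one$gsw, "linear")
  expect_equal(unname(fit$params["slope"]), resp$gs_slope, tolerance = 1e-6)
  # seed contract: bit-identical datasets
  d1 <- simulate_vpd_response(p, resp, seed = 42)
  d2 <- simulate_vpd_response(p, resp, seed = 42)
  expect_identical(d1, d2)
  d3 <- simulate_vpd_response(p, resp, seed = 43)
  expect_false(identical(d1$pn, d3$pn))
})

test_that("simulation refuses grids where conductances go non-positive", {
  p <- default_params()
  expect_error(
    simulate_vpd_response(p, vpd_response_params("LVPD"),
                          vpd_grid = c(0.5, 5.0), noise = FALSE),
    "non-positive")
})

test_that("fluorescence phi_psii reproduces the actual electron transport", {
  p <- default_params()
  d <- simulate_vpd_response(p, vpd_response_params("HVPD"), noise = FALSE)
  j_est <- electron_transport_rate(d$phi_psii, d$ppfd)
  expect_equal(j_est, d$j_flu, tolerance = 1e-12)
  # RuBP-limited records carry the light-response J
  jpot <- j_light_response(1100, p$jmax, p$alpha_j, p$theta_j)
  rubp <- d$limitation == "rubp"
  expect_equal(d$j_flu[rubp], rep(jpot, sum(rubp)), tolerance = 1e-9)
  expect_true(all(d$j_flu[!rubp] < jpot))
})
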