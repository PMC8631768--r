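test_that("the three regression forms recover noiseless truth exactly", {
  x <- c(0.5, 1.5, 2.5, 3.5, 4.5)
  lin <- fit_response(x, -0.2 * x + 0.928, "linear")
  expect_equal(unname(lin$params), c(-0.2, 0.928), tolerance = 1e-12)
  expect_equal(lin$r2, 1)

  logf <- fit_response(x, 50.82 * log(x) + 109.95, "logarithmic")
  expect_equal(unname(logf$params), c(50.82, 109.95), tolerance = 1e-10)

  expf <- fit_response(x, 301.3 * exp(0.15 * x), "exponential")
  expect_equal(unname(expf$params["scale"]), 301.3, tolerance = 1e-10)
  expect_equal(unname(expf$params["rate"]), 0.15, tolerance = 1e-12)
  expect_equal(expf$r2, 1)
  expect_equal(expf$r2_natural, 1, tolerance = 1e-10)
  # exactness in the transformed domain
  pred <- expf$params["scale"] * exp(expf$params["rate"] * x)
  expect_lt(max(abs(log(pred) - log(301.3 * exp(0.15 * x)))), 1e-10)
})

test_that("degenerate and out-of-domain inputs are handled per form", {
  x <- 1:5
  const <- fit_response(x, rep(3, 5), "linear")
  expect_equal(unname(const$params["slope"]), 0)
  expect_equal(const$r2, 0)
  expect_error(fit_response(c(-1, 1, 2), c(1, 2, 3), "logarithmic"), "x > 0")
  expect_error(fit_response(x, c(-1, 1, 2, 3, 4), "exponential"), "y > 0")
  expect_error(fit_response(1:2, 1:2, "linear"), ">= 3")
})

test_that("linear fits are affine-equivariant in the response", {
  set.seed(11)
  x <- stats::runif(20, 0, 5)
  y <- -0.18 * x + 0.9 + stats::rnorm(20, sd = 0.05)
  f1 <- fit_response(x, y, "linear")
  f2 <- fit_response(x, 7 * y, "linear")
  expect_equal(unname(f2$params), 7 * unname(f1$params), tolerance = 1e-10)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-12)
})

test_that("slope comparison identifies the shallower VPD response", {
  x <- c(0.5, 1.5, 2.5, 3.5, 4.5)
  a <- fit_response(x, -0.187 * x + 0.895, "linear")  # high-VPD-grown
  b <- fit_response(x, -0.200 * x + 0.928, "linear")  # low-VPD-grown
  cmp <- compare_slopes(a, b)
  expect_equal(cmp$difference, 0.013, tolerance = 1e-10)
  expect_equal(cmp$direction, "a shallower")

  same <- compare_slopes(a, a)
  expect_equal(same$difference, 0)
  expect_equal(same$direction, "indistinguishable")

  lg <- fit_response(x, 50 * log(x) + 100, "logarithmic")
  expect_error(compare_slopes(a, lg), "linear")
})

test_that("correlation is exact, symmetric and bounded under independence", {
  u <- 1:10
  ct <- correlate(u, -2 * u + 1)
  expect_equal(ct$r, -1, tolerance = 1e-12)
  expect_equal(ct$slope, -2, tolerance = 1e-12)
  set.seed(202)
  a <- stats::rnorm(1000); b <- stats::rnorm(1000)
  expect_lt(abs(correlate(a, b)$r), 0.1)
  expect_equal(correlate(a, b)$r, correlate(b, a)$r, tolerance = 1e-12)
})

test_that("composed generator responses reproduce the gs~ABA relation", {
  # gs declining linearly and ABA rising exponentially in VPD compose to a
  # near-linear negative gs(ABA) relation with the published slope
  vpd <- seq(0.5, 4.5, by = 0.5)
  lv <- ref_vpd_trends("LVPD")
  gs <- predict_linear(lv$gs, vpd)
  aba <- lv$aba[1] * exp(lv$aba[2] * vpd)
  ct <- correlate(aba, gs)
  expect_lt(ct$r, -0.97)
  expect_lt(abs(ct$slope - (-0.0029)), 3e-4)
})
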