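#' Fit a VPD-response regression of a given functional form
#'
#' The three functional forms used to summarise VPD-response experiments:
#' linear (`y = a x + b`, OLS), logarithmic (`y = a ln(x) + b`, OLS on
#' `ln x`) and exponential (`y = scale exp(rate x)`, OLS of `ln y` on `x`
#' with back-transformed coefficients). For the exponential form, R2 is
#' reported on the fitted (log) scale, with the natural-scale R2 alongside.
#'
#' @param x Predictor values (e.g. VPD, kPa); must be > 0 for the
#'   logarithmic form.
#' @param y Response values; must be > 0 for the exponential form.
#' @param form `"linear"`, `"logarithmic"` or `"exponential"`.
#' @param labels Optional character vector `c(predictor, response)` carried
#'   into the result.
#' @return Object of class `"response_fit"`: `form`, `params`
#'   (`c(slope, intercept)` or `c(scale, rate)`), `r2`, `r2_scale`,
#'   `r2_natural` (exponential only), `n`, `labels`, and the underlying
#'   `lm` fit.
#' @export
#' @examples
#' fit_response(c(0.5, 1.5, 2.5, 3.5, 4.5),
#'              301.3 * exp(0.15 * c(0.5, 1.5, 2.5, 3.5, 4.5)),
#'              "exponential")
fit_response <- function(x, y, form = c("linear", "logarithmic", "exponential"),
                         labels = c("x", "y")) {
  form <- match.arg(form)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need >= 3 finite paired observations")
  if (form == "logarithmic" && any(x <= 0)) {
    stop("logarithmic form requires x > 0")
  }
  if (form == "exponential" && any(y <= 0)) {
    stop("exponential form requires y > 0")
  }
  r2_of <- function(fit, resp) {
    if (stats::var(resp) == 0) return(0)  # degenerate: no variance explained
    suppressWarnings(summary(fit)$r.squared)  # exact fits are legitimate here
  }
  if (form == "linear") {
    fit <- stats::lm(y ~ x)
    params <- c(slope = unname(stats::coef(fit)[2]),
                intercept = unname(stats::coef(fit)[1]))
    if (stats::var(y) == 0) params["slope"] <- 0
    out <- list(form = form, params = params, r2 = r2_of(fit, y),
                r2_scale = "natural", n = length(x), labels = labels,
                fit = fit)
  } else if (form == "logarithmic") {
    lx <- log(x)
    fit <- stats::lm(y ~ lx)
    params <- c(slope = unname(stats::coef(fit)[2]),
                intercept = unname(stats::coef(fit)[1]))
    out <- list(form = form, params = params, r2 = r2_of(fit, y),
                r2_scale = "natural (ln x predictor)", n = length(x),
                labels = labels, fit = fit)
  } else {
    ly <- log(y)
    fit <- stats::lm(ly ~ x)
    rate <- unname(stats::coef(fit)[2])
    scale <- exp(unname(stats::coef(fit)[1]))
    pred_nat <- scale * exp(rate * x)
    r2_nat <- if (stats::var(y) > 0) {
      1 - sum((y - pred_nat)^2) / sum((y - mean(y))^2)
    } else 0
    out <- list(form = form, params = c(scale = scale, rate = rate),
                r2 = r2_of(fit, ly), r2_scale = "log",
                r2_natural = r2_nat, n = length(x), labels = labels,
                fit = fit)
  }
  structure(out, class = "response_fit")
}

#' @export
print.response_fit <- function(x, ...) {
  eq <- switch(x$form,
    linear = sprintf("%s = %.4g %s + %.4g", x$labels[2], x$params[1],
                     x$labels[1], x$params[2]),
    logarithmic = sprintf("%s = %.4g ln(%s) + %.4g", x$labels[2],
                          x$params[1], x$labels[1], x$params[2]),
    exponential = sprintf("%s = %.4g exp(%.4g %s)", x$labels[2],
                          x$params[1], x$params[2], x$labels[1]))
  cat(sprintf("%s fit (n = %d): %s, R2 = %.3f (%s scale)\n",
              x$form, x$n, eq, x$r2, x$r2_scale))
  invisible(x)
}

#' Compare the slopes of two linear response fits
#'
#' Welch-style two-sided t comparison of the slope estimates of two
#' independent linear fits of the same variable pair, with a direction
#' label: the fit with the smaller |slope| is the "shallower" response.
#'
#' @param fit_a,fit_b `"response_fit"` objects of form `"linear"`.
#' @param alpha Significance level for the direction call.
#' @return List with `difference` (slope_a - slope_b), `se`, `t`, `df`
#'   (Welch-Satterthwaite), `p_value` and `direction` (`"a shallower"`,
#'   `"b shallower"` or `"indistinguishable"`).
#' @export
#' @examples
#' x <- c(0.5, 1.5, 2.5, 3.5, 4.5)
#' a <- fit_response(x, -0.187 * x + 0.895, "linear")
#' b <- fit_response(x, -0.200 * x + 0.928, "linear")
#' compare_slopes(a, b)$direction
compare_slopes <- function(fit_a, fit_b, alpha = 0.05) {
  if (!inherits(fit_a, "response_fit") || !inherits(fit_b, "response_fit") ||
      fit_a$form != "linear" || fit_b$form != "linear") {
    stop("compare_slopes requires two linear response fits")
  }
  sa <- suppressWarnings(summary(fit_a$fit)$coefficients)
  sb <- suppressWarnings(summary(fit_b$fit)$coefficients)
  slope_a <- sa[2, 1]; se_a <- sa[2, 2]
  slope_b <- sb[2, 1]; se_b <- sb[2, 2]
  diff <- slope_a - slope_b
  se <- sqrt(se_a^2 + se_b^2)
  dfa <- fit_a$n - 2; dfb <- fit_b$n - 2
  if (se == 0) {
    tval <- if (diff == 0) 0 else Inf
    df <- dfa + dfb
    p <- if (diff == 0) 1 else 0
  } else {
    tval <- diff / se
    df <- se^4 / (se_a^4 / dfa + se_b^4 / dfb)
    p <- 2 * stats::pt(-abs(tval), df)
  }
  direction <- if (p >= alpha && abs(diff) < .Machine$double.eps^0.5) {
    "indistinguishable"
  } else if (abs(slope_a) < abs(slope_b)) {
    "a shallower"
  } else if (abs(slope_b) < abs(slope_a)) {
    "b shallower"
  } else {
    "indistinguishable"
  }
  list(difference = diff, se = se, t = tval, df = df, p_value = p,
       direction = direction)
}

#' Pearson correlation with linear fit
#'
#' @param u,v Paired numeric vectors, n >= 3.
#' @return List with `r`, `p_value`, `slope`, `intercept`, `n`.
#' @export
#' @examples
#' correlate(1:10, -2 * (1:10) + 1)
correlate <- function(u, v) {
  keep <- is.finite(u) & is.finite(v)
  u <- u[keep]; v <- v[keep]
  if (length(u) < 3) stop("need >= 3 finite pairs")
  ct <- stats::cor.test(u, v, method = "pearson")
  fit <- stats::lm(v ~ u)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(u))
}
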