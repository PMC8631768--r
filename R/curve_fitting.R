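#' Carboxylation efficiency from the low-CO2 Pn-Ci slope
#'
#' Ordinary least squares of net photosynthesis on intercellular CO2,
#' restricted to records measured at ambient CO2 at or below `ca_max`
#' (default 200 umol mol-1). The slope is the carboxylation efficiency CE.
#'
#' @param curve Data.frame of A-Ci records with columns `pn`,
#'   `ci_umol_mol`, `ca_umol_mol`.
#' @param ca_max Ambient-CO2 cutoff defining the initial slope window,
#'   umol mol-1.
#' @return List with `ce` (slope, mol m-2 s-1), `intercept`
#'   (umol m-2 s-1), `r2` and `n`.
#' @export
#' @examples
#' curve <- generate_aci_curve(leaf_phys_params(), 0.25, 0.3,
#'                             environment_state())
#' fit_ce(curve)$ce
fit_ce <- function(curve, ca_max = 200) {
  sub <- curve[curve$ca_umol_mol <= ca_max, , drop = FALSE]
  if (nrow(sub) < 3) {
    stop("fit_ce needs >= 3 records with Ca <= ", ca_max,
         " umol mol-1 (got ", nrow(sub), ")")
  }
  fit <- stats::lm(pn ~ ci_umol_mol, data = sub)
  list(ce = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = suppressWarnings(summary(fit)$r.squared),
       n = nrow(sub))
}

#' @keywords internal
#' FvCB net assimilation on the Cc axis for given capacities.
fvcb_net_model <- function(cc, vcmax, jmax, rd, gamma_star, km, ppfd,
                           alpha, theta) {
  j <- j_light_response(ppfd, jmax, alpha, theta)
  ac <- vcmax * (cc - gamma_star) / (cc + km)
  aj <- j * (cc - gamma_star) / (4 * cc + 8 * gamma_star)
  pmin(ac, aj) - rd
}

#' Fit FvCB capacities Vcmax and Jmax to an A-Ci/A-Cc curve
#'
#' Nonlinear least squares of observed net photosynthesis against
#' `min(Ac, Aj) - Rd` on the chloroplastic CO2 axis when a `cc` column is
#' available, falling back to the Ci axis (equivalent to assuming infinite
#' mesophyll conductance) otherwise; the axis used is recorded. The fit is
#' grid-seeded (multi-start over `vcmax` in {25, 50, 100, 200} with
#' `jmax = 2 vcmax`) and deterministic given identical inputs.
#'
#' @param curve Data.frame with columns `pn` and either `cc_umol_mol` (or
#'   `cc_true`) or `ci_umol_mol`, plus `ppfd`.
#' @param rd,gamma_star,kc,ko,o2 Known FvCB constants (units as in
#'   [leaf_phys_params()]).
#' @param alpha,theta Light-response constants.
#' @param transition_guess Cc separating the "low" and "high" CO2 ranges
#'   used only to warn about poor identifiability coverage, umol mol-1.
#' @return Object of class `"photo_capacity"`: `vcmax`, `jmax`, `rd`,
#'   `gamma_star`, `axis` (`"cc"` or `"ci"`), `rmse`, `r2`, `n`,
#'   `limitation` (per-point state at the fitted parameters),
#'   `jmax_identifiable`, `ratio_flag` (TRUE when jmax/vcmax falls outside
#'   [0.5, 5]), and `converged`.
#' @export
#' @examples
#' curve <- generate_aci_curve(leaf_phys_params(), 0.25, 0.3,
#'                             environment_state())
#' curve$cc_umol_mol <- curve$cc_true
#' fit_fvcb(curve, rd = 1, gamma_star = 40)
fit_fvcb <- function(curve, rd, gamma_star, kc = 404, ko = 278, o2 = 210,
                     alpha = 0.3, theta = 0.9, transition_guess = 250) {
  cc_col <- intersect(c("cc_umol_mol", "cc_true"), names(curve))
  axis <- if (length(cc_col)) "cc" else "ci"
  x <- if (axis == "cc") curve[[cc_col[1]]] else curve$ci_umol_mol
  keep <- is.finite(x) & is.finite(curve$pn)
  x <- x[keep]
  pn <- curve$pn[keep]
  ppfd <- curve$ppfd[keep]
  if (length(x) < 4) stop("fit_fvcb needs >= 4 finite records")
  km <- kc * (1 + o2 / ko)
  n_low <- sum(x < transition_guess)
  n_high <- sum(x >= transition_guess)
  if (n_low < 2 || n_high < 2) {
    warning("curve poorly spans the transition guess (", transition_guess,
            " umol mol-1): ", n_low, " low / ", n_high, " high points")
  }
  dat <- data.frame(x = x, pn = pn, ppfd = ppfd)
  starts <- lapply(c(25, 50, 100, 200),
                   function(v) list(vcmax = v, jmax = 2 * v))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        pn ~ fvcb_net_model(x, vcmax, jmax, rd, gamma_star, km, ppfd,
                            alpha, theta),
        data = dat, start = s,
        lower = c(vcmax = 1, jmax = 1),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) {
    # Degenerate curves (a single active limitation branch) make the other
    # capacity's gradient vanish; fall back to one-parameter branch fits and
    # flag the unidentifiable parameter.
    ac_only <- tryCatch(
      minpack.lm::nlsLM(pn ~ vcmax * (x - gamma_star) / (x + km) - rd,
                        data = dat, start = list(vcmax = 100),
                        lower = c(vcmax = 1)),
      error = function(e) NULL)
    aj_only <- tryCatch(
      minpack.lm::nlsLM(
        pn ~ j_light_response(ppfd, jmax, alpha, theta) * (x - gamma_star) /
          (4 * x + 8 * gamma_star) - rd,
        data = dat, start = list(jmax = 150), lower = c(jmax = 1)),
      error = function(e) NULL)
    rss <- function(f) if (is.null(f)) Inf else sum(stats::residuals(f)^2)
    if (is.infinite(rss(ac_only)) && is.infinite(rss(aj_only))) {
      return(structure(list(converged = FALSE, axis = axis, n = length(x),
                            message = "no multi-start fit converged"),
                       class = "photo_capacity"))
    }
    branch <- if (rss(ac_only) <= rss(aj_only)) "rubisco" else "rubp"
    fit <- if (branch == "rubisco") ac_only else aj_only
    vcmax <- if (branch == "rubisco") unname(stats::coef(fit)["vcmax"]) else NA_real_
    jmax <- if (branch == "rubp") unname(stats::coef(fit)["jmax"]) else NA_real_
    fitted <- stats::fitted(fit)
    rmse <- sqrt(mean((pn - fitted)^2))
    r2 <- if (stats::var(pn) > 0) {
      1 - sum((pn - fitted)^2) / sum((pn - mean(pn))^2)
    } else 0
    return(structure(list(
      vcmax = vcmax, jmax = jmax, rd = rd, gamma_star = gamma_star,
      axis = axis, rmse = rmse, r2 = r2, n = length(x),
      limitation = rep(branch, length(x)),
      jmax_identifiable = branch == "rubp",
      vcmax_identifiable = branch == "rubisco",
      ratio_flag = NA, converged = TRUE
    ), class = "photo_capacity"))
  }
  cf <- stats::coef(best$fit)
  vcmax <- unname(cf["vcmax"])
  jmax <- unname(cf["jmax"])
  j <- j_light_response(ppfd, jmax, alpha, theta)
  ac <- vcmax * (x - gamma_star) / (x + km)
  aj <- j * (x - gamma_star) / (4 * x + 8 * gamma_star)
  limitation <- ifelse(ac <= aj, "rubisco", "rubp")
  fitted <- pmin(ac, aj) - rd
  rmse <- sqrt(mean((pn - fitted)^2))
  r2 <- if (stats::var(pn) > 0) {
    1 - sum((pn - fitted)^2) / sum((pn - mean(pn))^2)
  } else 0
  structure(list(
    vcmax = vcmax, jmax = jmax, rd = rd, gamma_star = gamma_star,
    axis = axis, rmse = rmse, r2 = r2, n = length(x),
    limitation = limitation,
    jmax_identifiable = any(limitation == "rubp"),
    vcmax_identifiable = any(limitation == "rubisco"),
    ratio_flag = (jmax / vcmax < 0.5 || jmax / vcmax > 5),
    converged = TRUE
  ), class = "photo_capacity")
}

#' @export
print.photo_capacity <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("FvCB capacity fit: FAILED (", x$message, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("FvCB capacity fit on the %s axis (n = %d):\n", x$axis, x$n))
  cat(sprintf("  Vcmax %.2f, Jmax %.2f umol m-2 s-1 (Rd %.2f, Gamma* %.1f fixed)\n",
              x$vcmax, x$jmax, x$rd, x$gamma_star))
  cat(sprintf("  RMSE %.3g, R2 %.4f; %d Rubisco- / %d RuBP-limited points\n",
              x$rmse, x$r2, sum(x$limitation == "rubisco"),
              sum(x$limitation == "rubp")))
  if (!x$jmax_identifiable) cat("  warning: no RuBP-limited points; Jmax unidentifiable\n")
  if (x$ratio_flag) cat("  warning: Jmax/Vcmax outside [0.5, 5]\n")
  invisible(x)
}

#' Laisk two-light intersection estimate of Gamma* and Rd
#'
#' Fits an ordinary least-squares line `Pn = a Ci + b` to each of two
#' low-CO2 response curves measured at different light intensities and
#' returns their intersection: the x-coordinate as the photocompensation
#' point Gamma* and minus the y-coordinate as day respiration Rd (reported
#' positive). Exactly solvable and seed-free.
#'
#' Because the intersection is located on the Ci axis while Gamma* is
#' defined at the chloroplast, the estimate carries a bias of order
#' `Rd / gm`; the gap is reported in `diagnostics` rather than corrected.
#'
#' @param curve_low,curve_high Data.frames of records (columns `pn`,
#'   `ci_umol_mol`) at the lower and higher light level.
#' @param ci_range Optional `c(min, max)` ambient-CO2 window filter applied
#'   when a `ca_umol_mol` column is present (default 30-120 umol mol-1).
#' @param slope_tol Minimum slope difference below which the lines are
#'   declared parallel.
#' @return List with `gamma_star` (umol mol-1), `rd` (umol m-2 s-1) and
#'   `diagnostics` (per-curve slopes/intercepts/r2 and n).
#' @export
#' @examples
#' d <- generate_laisk_dataset(leaf_phys_params(), 0.25, 10,
#'                             environment_state())
#' laisk_intersection(d[d$light_level == 75, ], d[d$light_level == 500, ])
laisk_intersection <- function(curve_low, curve_high, ci_range = c(30, 120),
                               slope_tol = 1e-8) {
  filt <- function(d) {
    if ("ca_umol_mol" %in% names(d)) {
      d <- d[d$ca_umol_mol >= ci_range[1] & d$ca_umol_mol <= ci_range[2], ,
             drop = FALSE]
    }
    d
  }
  curve_low <- filt(curve_low)
  curve_high <- filt(curve_high)
  if (nrow(curve_low) < 3 || nrow(curve_high) < 3) {
    stop("need >= 3 points per curve within the low-CO2 window")
  }
  f1 <- stats::lm(pn ~ ci_umol_mol, data = curve_low)
  f2 <- stats::lm(pn ~ ci_umol_mol, data = curve_high)
  a1 <- stats::coef(f1)[2]; b1 <- stats::coef(f1)[1]
  a2 <- stats::coef(f2)[2]; b2 <- stats::coef(f2)[1]
  if (abs(a1 - a2) < slope_tol) {
    stop("parallel lines, no intersection: slope difference below tolerance")
  }
  x_star <- unname((b2 - b1) / (a1 - a2))
  rd <- unname(-(a1 * x_star + b1))
  list(gamma_star = x_star, rd = rd,
       diagnostics = data.frame(
         curve = c("low", "high"),
         slope = c(unname(a1), unname(a2)),
         intercept = c(unname(b1), unname(b2)),
         r2 = suppressWarnings(c(summary(f1)$r.squared, summary(f2)$r.squared)),
         n = c(nrow(curve_low), nrow(curve_high))))
}
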