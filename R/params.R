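#' Biochemical parameters of the FvCB leaf model
#'
#' Constructs and validates the parameter set of the
#' Farquhar-von Caemmerer-Berry (FvCB) C3 photosynthesis model used by the
#' steady-state simulator and the capacity fits. Kinetic constants default to
#' widely used tobacco-derived values on a mole-fraction basis; no
#' temperature response is applied (measurements are taken at a single
#' cabinet temperature), so `kc`, `ko` and `gamma_star` are
#' at-measurement-temperature inputs.
#'
#' The default `vcmax`/`jmax` pair is chosen so that the simulated leaf is
#' RuBP-regeneration-limited at the standard measurement environment
#' (saturating light, ambient CO2), the operating state assumed by the
#' variable-J method.
#'
#' @param vcmax Maximum Rubisco carboxylation rate, umol m-2 s-1.
#' @param jmax Maximum electron transport rate, umol m-2 s-1.
#' @param rd Day (mitochondrial) respiration, umol m-2 s-1.
#' @param gamma_star Chloroplastic CO2 photocompensation point, umol mol-1.
#' @param kc Michaelis constant of Rubisco for CO2, umol mol-1.
#' @param ko Michaelis constant of Rubisco for O2, mmol mol-1.
#' @param o2 Oxygen mole fraction, mmol mol-1.
#' @param theta_j Curvature of the electron transport light response, in (0, 1].
#' @param alpha_j Apparent quantum yield of electron transport,
#'   mol e- per mol photons.
#' @return An object of class `"leaf_phys_params"` (named list).
#' @export
#' @examples
#' leaf_phys_params()
#' leaf_phys_params(vcmax = 80, jmax = 140)
leaf_phys_params <- function(vcmax = 110, jmax = 140, rd = 1,
                             gamma_star = 40, kc = 404, ko = 278,
                             o2 = 210, theta_j = 0.9, alpha_j = 0.3) {
  p <- list(vcmax = vcmax, jmax = jmax, rd = rd, gamma_star = gamma_star,
            kc = kc, ko = ko, o2 = o2, theta_j = theta_j, alpha_j = alpha_j)
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("all FvCB parameters must be finite numeric scalars; offending: ",
         paste(names(p)[!num], collapse = ", "))
  }
  if (any(unlist(p) <= 0)) {
    stop("all FvCB parameters must be strictly positive; offending: ",
         paste(names(p)[unlist(p) <= 0], collapse = ", "))
  }
  if (theta_j > 1) stop("theta_j must lie in (0, 1]")
  if (jmax <= rd) stop("jmax must exceed rd")
  structure(p, class = "leaf_phys_params")
}

#' @export
print.leaf_phys_params <- function(x, ...) {
  cat("FvCB leaf parameters:\n")
  cat(sprintf("  Vcmax %.4g, Jmax %.4g, Rd %.4g umol m-2 s-1\n",
              x$vcmax, x$jmax, x$rd))
  cat(sprintf("  Gamma* %.4g, Kc %.4g umol mol-1; Ko %.4g, O2 %.4g mmol mol-1\n",
              x$gamma_star, x$kc, x$ko, x$o2))
  cat(sprintf("  light response: theta %.3g, alpha %.3g\n", x$theta_j, x$alpha_j))
  invisible(x)
}

#' Ambient conditions of one steady-state measurement
#'
#' @param vpd Leaf-to-air vapour pressure deficit, kPa.
#' @param t_leaf Leaf temperature, degrees C.
#' @param ppfd Photosynthetic photon flux density, umol m-2 s-1.
#' @param ca Ambient CO2 mole fraction, umol mol-1.
#' @param o2 Oxygen mole fraction, mmol mol-1.
#' @return An object of class `"environment_state"` (named list).
#' @export
#' @examples
#' environment_state(vpd = 1.5)
environment_state <- function(vpd = 1.5, t_leaf = 28, ppfd = 1100,
                              ca = 400, o2 = 210) {
  if (!is.numeric(vpd) || vpd < 0) stop("vpd must be >= 0 kPa")
  if (!is.numeric(ca) || ca <= 0) stop("ca must be > 0 umol mol-1")
  if (!is.numeric(ppfd) || ppfd < 0) stop("ppfd must be >= 0")
  structure(list(vpd = vpd, t_leaf = t_leaf, ppfd = ppfd, ca = ca, o2 = o2),
            class = "environment_state")
}

#' VPD-response parameters of the synthetic study
#'
#' Empirical response functions that drive the synthetic-leaf generator
#' across a VPD gradient: linear declines of stomatal (`gs`, water-vapour
#' basis) and mesophyll (`gm`) conductance, an exponential rise of foliar
#' ABA, and a linear decline of leaf water potential. Defaults are the
#' regime-specific reference coefficients of [ref_vpd_trends()].
#'
#' @param regime `"HVPD"` or `"LVPD"` growth regime label; selects default
#'   coefficients.
#' @param cultivar Free-text cultivar label.
#' @param gs_slope,gs_intercept Linear gsw(VPD), mol m-2 s-1 per kPa and
#'   mol m-2 s-1; slope must be <= 0.
#' @param gm_slope,gm_intercept Linear gm(VPD), same units; slope <= 0.
#' @param aba_scale,aba_rate Exponential ABA(VPD) = scale * exp(rate * VPD),
#'   ng g-1 and kPa-1; rate >= 0.
#' @param psi_leaf_slope,psi_leaf_intercept Linear leaf water potential
#'   response, MPa per kPa and MPa; slope <= 0.
#' @param psi_soil Soil water potential, MPa (constant across the gradient).
#' @param lma Leaf mass per area, g m-2.
#' @param noise_cv Named numeric: multiplicative Gaussian coefficients of
#'   variation for `pn` and `gsw` observations.
#' @return An object of class `"vpd_response_params"` (named list).
#' @export
#' @examples
#' vpd_response_params("LVPD")
vpd_response_params <- function(regime = c("HVPD", "LVPD"),
                                cultivar = "CV1",
                                gs_slope = NULL, gs_intercept = NULL,
                                gm_slope = NULL, gm_intercept = NULL,
                                aba_scale = NULL, aba_rate = NULL,
                                psi_leaf_slope = NULL, psi_leaf_intercept = NULL,
                                psi_soil = NULL,
                                lma = NULL,
                                noise_cv = c(pn = 0.02, gsw = 0.05)) {
  regime <- match.arg(regime)
  ref <- ref_vpd_trends(regime)
  gs_slope <- gs_slope %||% ref$gs[1]
  gs_intercept <- gs_intercept %||% ref$gs[2]
  gm_slope <- gm_slope %||% ref$gm[1]
  gm_intercept <- gm_intercept %||% ref$gm[2]
  aba_scale <- aba_scale %||% ref$aba[1]
  aba_rate <- aba_rate %||% ref$aba[2]
  psi_leaf_slope <- psi_leaf_slope %||% ref$psi_leaf[1]
  psi_leaf_intercept <- psi_leaf_intercept %||% ref$psi_leaf[2]
  # Psi_soil from caption algebra: psi_leaf intercept + delta(soil-leaf) intercept
  psi_soil <- psi_soil %||% (ref$psi_leaf[2] + ref$delta_soil_leaf[2])
  lma <- lma %||% if (regime == "HVPD") 35 else 32
  if (gs_slope > 0 || gm_slope > 0) stop("gs_slope and gm_slope must be <= 0")
  if (aba_rate < 0) stop("aba_rate must be >= 0")
  if (psi_leaf_slope > 0) stop("psi_leaf_slope must be <= 0")
  if (!all(c("pn", "gsw") %in% names(noise_cv))) {
    stop("noise_cv must name 'pn' and 'gsw'")
  }
  structure(list(
    regime = regime, cultivar = cultivar,
    gs_slope = gs_slope, gs_intercept = gs_intercept,
    gm_slope = gm_slope, gm_intercept = gm_intercept,
    aba_scale = aba_scale, aba_rate = aba_rate,
    psi_leaf_slope = psi_leaf_slope, psi_leaf_intercept = psi_leaf_intercept,
    psi_soil = psi_soil, lma = lma,
    noise_cv = noise_cv
  ), class = "vpd_response_params")
}

#' @export
print.vpd_response_params <- function(x, ...) {
  cat(sprintf("VPD response set [%s, %s]:\n", x$regime, x$cultivar))
  cat(sprintf("  gsw = %.4g VPD + %.4g  (mol m-2 s-1)\n", x$gs_slope, x$gs_intercept))
  cat(sprintf("  gm  = %.4g VPD + %.4g  (mol m-2 s-1)\n", x$gm_slope, x$gm_intercept))
  cat(sprintf("  ABA = %.4g exp(%.3g VPD)  (ng g-1)\n", x$aba_scale, x$aba_rate))
  cat(sprintf("  Psi_leaf = %.4g VPD + %.4g MPa; Psi_soil %.4g MPa; LMA %.4g g m-2\n",
              x$psi_leaf_slope, x$psi_leaf_intercept, x$psi_soil, x$lma))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
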