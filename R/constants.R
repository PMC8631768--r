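#' Physical and instrument constants
#'
#' Named constants shared across the package: the water/CO2 gas-phase
#' diffusivity ratio used to convert stomatal conductance between bases, the
#' leaf absorptance and PSII partitioning fraction used to derive electron
#' transport from fluorescence, the universal gas constant and the molar
#' volume of liquid water used for air water potential.
#'
#' @return Named list of constants:
#' \describe{
#'   \item{diffusivity_ratio}{gsw/gsc ratio of molecular diffusivities of
#'     water vapour and CO2 in air (1.6, dimensionless).}
#'   \item{absorptance}{leaf absorptance used in the fluorescence J
#'     calculation (0.84).}
#'   \item{psii_fraction}{fraction of absorbed quanta reaching PSII (0.5).}
#'   \item{gas_constant}{8.314 J mol-1 K-1.}
#'   \item{water_molar_volume}{1.805e-5 m3 mol-1.}
#' }
#' @export
#' @examples
#' photo_constants()$diffusivity_ratio
photo_constants <- function() {
  list(
    diffusivity_ratio  = 1.6,
    absorptance        = 0.84,
    psii_fraction      = 0.5,
    gas_constant       = 8.314,     # J mol-1 K-1
    water_molar_volume = 1.805e-5   # m3 mol-1
  )
}

#' Reference VPD-response regression coefficients
#'
#' Empirical figure-caption regressions for greenhouse tomato acclimated to
#' high (HVPD) or low (LVPD) vapour pressure deficit, used both as the
#' default ground truth of the synthetic-leaf generator and as the
#' "regression passthrough" inputs for worked-example reproductions.
#' All linear entries are `c(slope, intercept)` on the stated units;
#' `aba` is `c(scale, rate)` of an exponential ABA = scale * exp(rate * VPD);
#' `ratio_lnvpd` is `c(slope, intercept)` on ln(VPD).
#'
#' @param regime `"HVPD"` or `"LVPD"`.
#' @return Named list of coefficient vectors: `gs` (mol m-2 s-1 per kPa),
#'   `gm`, `gtot`, `ci`, `cc`, `ci_over_ca`, `cc_over_ca`, `cc_over_ci`,
#'   `ls`, `lm`, `psi_leaf` (MPa per kPa), `delta_soil_leaf`,
#'   `delta_leaf_air`, `ratio_lnvpd`, `aba` (ng g-1, kPa-1),
#'   `gs_vs_aba`, `gm_vs_aba`.
#' @export
#' @examples
#' ref_vpd_trends("LVPD")$ls
ref_vpd_trends <- function(regime = c("HVPD", "LVPD")) {
  regime <- match.arg(regime)
  if (regime == "HVPD") {
    list(
      gs              = c(-0.187,  0.895),
      gm              = c(-0.126,  0.661),
      gtot            = c(-0.0719, 0.365),
      ci              = c(-17.2,   371.6),
      cc              = c(-31.5,   331.6),
      ci_over_ca      = c(-0.0429, 0.93),
      cc_over_ca      = c(-0.0788, 0.83),
      cc_over_ci      = c(-0.0537, 0.89),
      ls              = c(0.0472,  0.122),
      lm              = c(0.0266,  0.208),
      psi_leaf        = c(-0.242, -0.358),
      delta_soil_leaf = c(0.242,   0.118),
      delta_leaf_air  = c(49.8,   -6.86),
      ratio_lnvpd     = c(50.82,   109.95),
      aba             = c(301.3,   0.15),
      gs_vs_aba       = c(-0.0029, 1.76),
      gm_vs_aba       = c(-0.0019, 1.19)
    )
  } else {
    list(
      gs              = c(-0.200,  0.928),
      gm              = c(-0.129,  0.658),
      gtot            = c(-0.0798, 0.384),
      ci              = c(-22,     377.6),
      cc              = c(-33.5,   332.2),
      ci_over_ca      = c(-0.055,  0.94),
      cc_over_ca      = c(-0.0837, 0.83),
      cc_over_ci      = c(-0.058,  0.91),
      ls              = c(0.0535,  0.115),
      lm              = c(0.0305,  0.197),
      psi_leaf        = c(-0.258, -0.347),
      delta_soil_leaf = c(0.251,   0.13),
      delta_leaf_air  = c(49.8,   -6.86),
      ratio_lnvpd     = c(48.63,   110.41),
      aba             = c(301.3,   0.15),
      gs_vs_aba       = c(-0.0029, 1.76),
      gm_vs_aba       = c(-0.0019, 1.19)
    )
  }
}

#' Evaluate a linear trend `c(slope, intercept)` at `x`
#'
#' Convenience for regression-passthrough analyses that evaluate published
#' `c(slope, intercept)` coefficient pairs (as returned by
#' [ref_vpd_trends()]) at chosen predictor values.
#'
#' @param coef Numeric length-2 vector `c(slope, intercept)`.
#' @param x Predictor values.
#' @return `coef[1] * x + coef[2]`.
#' @export
#' @examples
#' predict_linear(ref_vpd_trends("LVPD")$ls, 4.5)
predict_linear <- function(coef, x) {
  stopifnot(is.numeric(coef), length(coef) == 2L, is.numeric(x))
  coef[1] * x + coef[2]
}
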