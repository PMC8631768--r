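#' Air water potential from VPD
#'
#' Thermodynamic (Kelvin-equation) water potential of air,
#' `Psi_air = (R T / Vw) ln(RH)` with relative humidity
#' `RH = 1 - VPD / es(T)` and saturation vapour pressure from the Tetens
#' formula `es(T) = 0.6108 exp(17.27 T / (T + 237.3))` kPa. A linearised
#' mode `Psi_air = -(R T / Vw) VPD / es(T)` (the first-order expansion of
#' the logarithm) is selectable for comparison with linear-in-VPD empirical
#' driving-force regressions.
#'
#' @param vpd Vapour pressure deficit, kPa (vectorised); must satisfy
#'   `0 <= vpd < es(t_air)`.
#' @param t_air Air temperature, degrees C.
#' @param mode `"kelvin"` (default) or `"linear"`.
#' @param constants [photo_constants()].
#' @return Psi_air, MPa (<= 0).
#' @export
#' @examples
#' air_water_potential(1.0, 28)
air_water_potential <- function(vpd, t_air = 28,
                                mode = c("kelvin", "linear"),
                                constants = photo_constants()) {
  mode <- match.arg(mode)
  es <- 0.6108 * exp(17.27 * t_air / (t_air + 237.3))
  if (any(vpd < 0)) stop("vpd must be >= 0")
  if (any(vpd >= es)) {
    stop("super-saturation-impossible VPD at this temperature (es = ",
         signif(es, 4), " kPa)")
  }
  scale <- constants$gas_constant * (t_air + 273.15) /
    constants$water_molar_volume / 1e6  # MPa
  if (mode == "kelvin") {
    scale * log(1 - vpd / es)
  } else {
    -scale * vpd / es
  }
}

#' Water-potential driving forces along the soil-plant-atmosphere continuum
#'
#' Computes the soil-to-leaf and leaf-to-air water potential differences
#' and their ratio. The ratio is flagged undefined (`NA`) when the
#' soil-leaf difference is non-positive; a leaf wetter than the soil is
#' flagged, not fatal.
#'
#' @param psi_soil,psi_leaf,psi_air Water potentials, MPa (vectorised).
#' @param vpd,t_air Optional condition labels carried through.
#' @return Data.frame with `psi_soil`, `psi_leaf`, `psi_air`,
#'   `delta_soil_leaf`, `delta_leaf_air`, `ratio_leaf_air_to_soil_leaf`,
#'   `flag` (`"ok"` or `"soil_leaf_nonpositive"`), `vpd`, `t_air`.
#' @export
#' @examples
#' driving_forces(-0.24, -0.48, -42.6)
driving_forces <- function(psi_soil, psi_leaf, psi_air,
                           vpd = NA_real_, t_air = NA_real_) {
  if (any(!is.finite(psi_soil)) || any(!is.finite(psi_leaf)) ||
      any(!is.finite(psi_air))) {
    stop("water potentials must be finite")
  }
  d_sl <- psi_soil - psi_leaf
  d_la <- psi_leaf - psi_air
  bad <- d_sl <= 0
  ratio <- ifelse(bad, NA_real_, d_la / d_sl)
  data.frame(psi_soil = psi_soil, psi_leaf = psi_leaf, psi_air = psi_air,
             delta_soil_leaf = d_sl, delta_leaf_air = d_la,
             ratio_leaf_air_to_soil_leaf = ratio,
             flag = ifelse(bad, "soil_leaf_nonpositive", "ok"),
             vpd = vpd, t_air = t_air,
             stringsAsFactors = FALSE)
}

#' Soil water potential from predawn (dark-equilibrated) leaf measurements
#'
#' Under darkness water flow is near zero, so leaf xylem pressure potential
#' equilibrates with the soil; the soil water potential is estimated as the
#' mean of dark-equilibrated leaf measurements.
#'
#' @param dark_psi_leaf Numeric vector of dark-period leaf xylem potentials,
#'   MPa.
#' @return List with `psi_soil` (mean, MPa), `sd` and `n`.
#' @export
#' @examples
#' predawn_soil_potential(c(-0.22, -0.24, -0.26))
predawn_soil_potential <- function(dark_psi_leaf) {
  dark_psi_leaf <- dark_psi_leaf[is.finite(dark_psi_leaf)]
  if (!length(dark_psi_leaf)) {
    stop("need at least one dark-equilibrated leaf potential")
  }
  list(psi_soil = mean(dark_psi_leaf),
       sd = if (length(dark_psi_leaf) > 1) stats::sd(dark_psi_leaf) else NA_real_,
       n = length(dark_psi_leaf))
}

#' Driving-force ratio from published component regressions
#'
#' Regression-passthrough mode: evaluates user-supplied linear
#' `c(slope, intercept)` coefficient pairs for the leaf-air and soil-leaf
#' driving forces at given VPD values and returns their ratio. This keeps
#' worked-example reproduction independent of the thermodynamic VPD-to-
#' potential conversion.
#'
#' @param vpd VPD values, kPa.
#' @param leaf_air_coef,soil_leaf_coef Linear coefficients
#'   `c(slope, intercept)` in MPa per kPa and MPa, e.g. from
#'   [ref_vpd_trends()].
#' @return Numeric vector of ratios.
#' @export
#' @examples
#' tr <- ref_vpd_trends("HVPD")
#' driving_force_ratio_from_trends(4.5, tr$delta_leaf_air, tr$delta_soil_leaf)
driving_force_ratio_from_trends <- function(vpd, leaf_air_coef,
                                            soil_leaf_coef) {
  d_la <- predict_linear(leaf_air_coef, vpd)
  d_sl <- predict_linear(soil_leaf_coef, vpd)
  ifelse(d_sl <= 0, NA_real_, d_la / d_sl)
}
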