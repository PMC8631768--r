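#' Stomatal conductance on the CO2 basis
#'
#' Converts stomatal conductance to water vapour into stomatal conductance
#' to CO2 using the ratio of gas-phase molecular diffusivities.
#'
#' @param gsw Stomatal conductance to water vapour, mol m-2 s-1 (vectorised).
#' @param ratio Water/CO2 diffusivity ratio (default 1.6).
#' @return gsc = gsw / ratio, mol m-2 s-1.
#' @export
#' @examples
#' stomatal_conductance_co2(0.16)
stomatal_conductance_co2 <- function(gsw, ratio = photo_constants()$diffusivity_ratio) {
  if (any(!is.finite(gsw)) || any(gsw <= 0)) {
    stop("gsw must be strictly positive")
  }
  gsw / ratio
}

#' Electron transport rate from fluorescence
#'
#' Fluorescence-based electron transport rate
#' `J = phi_PSII * PPFD * absorptance * psii_fraction`.
#'
#' @param phi_psii PSII operating efficiency, in `[0, 1]` (vectorised).
#' @param ppfd Photon flux density, umol m-2 s-1.
#' @param absorptance Leaf absorptance (default 0.84).
#' @param psii_fraction Fraction of absorbed quanta at PSII (default 0.5).
#' @return J, umol m-2 s-1.
#' @export
#' @examples
#' electron_transport_rate(0.5, 1100)
electron_transport_rate <- function(phi_psii, ppfd,
                                    absorptance = photo_constants()$absorptance,
                                    psii_fraction = photo_constants()$psii_fraction) {
  if (any(phi_psii < 0 | phi_psii > 1, na.rm = TRUE)) {
    stop("phi_psii must lie in [0, 1]")
  }
  if (any(ppfd < 0)) stop("ppfd must be >= 0")
  if (absorptance <= 0 || absorptance > 1 || psii_fraction <= 0 || psii_fraction > 1) {
    stop("absorptance and psii_fraction must lie in (0, 1]")
  }
  phi_psii * ppfd * absorptance * psii_fraction
}

#' Variable-J estimator of mesophyll conductance
#'
#' Estimates mesophyll conductance from simultaneous gas exchange and
#' fluorescence:
#' `gm = Pn / (Ci - Gamma* (J + 8 (Pn + Rd)) / (J - 4 (Pn + Rd)))`.
#' The subtracted term is the chloroplastic CO2 implied by inverting the
#' RuBP-regeneration-limited assimilation expression at the measured J.
#'
#' A non-positive denominator (measured Ci at or below the implied Cc)
#' yields a flagged `NA` estimate rather than an error, so invalid points
#' propagate visibly through downstream summaries.
#'
#' @param pn Net photosynthesis, umol m-2 s-1 (vectorised); must be > 0.
#' @param ci Intercellular CO2, umol mol-1.
#' @param j Electron transport rate, umol m-2 s-1; must exceed
#'   `4 (pn + rd)`.
#' @param rd Day respiration, umol m-2 s-1.
#' @param gamma_star Photocompensation point, umol mol-1.
#' @return Numeric vector of gm estimates, mol m-2 s-1, with `NA` where the
#'   denominator was non-positive.
#' @export
#' @examples
#' variable_j_gm(pn = 20, ci = 300, j = 150, rd = 1, gamma_star = 40)
variable_j_gm <- function(pn, ci, j, rd, gamma_star) {
  if (any(pn <= 0, na.rm = TRUE)) {
    stop("variable-J estimation requires pn > 0")
  }
  if (any(j <= 4 * (pn + rd), na.rm = TRUE)) {
    stop("electron transport inconsistent with assimilation: need j > 4 (pn + rd)")
  }
  cc_implied <- gamma_star * (j + 8 * (pn + rd)) / (j - 4 * (pn + rd))
  denom <- ci - cc_implied
  gm <- pn / denom
  invalid <- !is.na(denom) & denom <= 0
  if (any(invalid)) {
    warning(sum(invalid),
            " record(s) with Ci at or below the implied Cc flagged NA")
    gm[invalid] <- NA_real_
  }
  gm
}

#' Total CO2 diffusion conductance of the series circuit
#'
#' Harmonic combination `1/gtot = 1/gsc + 1/gm` of the stomatal and
#' mesophyll conductances in series.
#'
#' @param gsc,gm Conductances, mol m-2 s-1 (vectorised); both > 0.
#' @return gtot, mol m-2 s-1; always below `min(gsc, gm)`.
#' @export
#' @examples
#' total_conductance(0.25, 0.30)
total_conductance <- function(gsc, gm) {
  if (any(gsc <= 0, na.rm = TRUE) || any(gm <= 0, na.rm = TRUE)) {
    stop("conductances must be strictly positive")
  }
  1 / (1 / gsc + 1 / gm)
}

#' Chloroplastic CO2 mole fraction
#'
#' Fick's law across the mesophyll: `Cc = Ci - Pn / gm`. `Cc` exceeds `Ci`
#' when `Pn < 0` (net efflux).
#'
#' @param pn Net photosynthesis, umol m-2 s-1 (vectorised).
#' @param ci Intercellular CO2, umol mol-1.
#' @param gm Mesophyll conductance, mol m-2 s-1; > 0.
#' @return Cc, umol mol-1.
#' @export
#' @examples
#' chloroplast_co2(20, 300, 0.1864)
chloroplast_co2 <- function(pn, ci, gm) {
  if (any(gm <= 0, na.rm = TRUE)) stop("gm must be strictly positive")
  ci - pn / gm
}

#' CO2 transport ratios along the source-path-sink
#'
#' @param ca,ci,cc Ambient, intercellular and chloroplastic CO2,
#'   umol mol-1 (vectorised); all > 0.
#' @return data.frame with `ci_over_ca`, `cc_over_ca`, `cc_over_ci`.
#' @export
#' @examples
#' transport_ratios(400, 350, 280)
transport_ratios <- function(ca, ci, cc) {
  if (any(c(ca, ci, cc) <= 0, na.rm = TRUE)) {
    stop("ca, ci and cc must be strictly positive")
  }
  data.frame(ci_over_ca = ci / ca, cc_over_ca = cc / ca, cc_over_ci = cc / ci)
}

#' Variable-J gm from a replicate set via mean observables
#'
#' Averages the observables (`pn`, `gsw`, `ci_umol_mol`, `phi_psii`,
#' `ppfd`) over a set of replicate records of the same leaf state and
#' applies the variable-J estimator once to the means. Because the
#' estimator is strongly nonlinear in `pn`, inverting the replicate means
#' (as derived quantities are conventionally computed from treatment
#' means) is far less noise-skewed than averaging per-replicate estimates.
#'
#' @param records Data.frame of replicate gas-exchange records.
#' @param rd,gamma_star Day respiration and photocompensation point.
#' @param constants [photo_constants()].
#' @return Single gm estimate, mol m-2 s-1 (`NA` if invalid).
#' @export
#' @examples
#' d <- simulate_vpd_response(leaf_phys_params(), vpd_response_params("LVPD"),
#'                            vpd_grid = 1.5, noise = FALSE)
#' gm_from_replicates(d, rd = 1, gamma_star = 40)
gm_from_replicates <- function(records, rd, gamma_star,
                               constants = photo_constants()) {
  req <- c("pn", "gsw", "ci_umol_mol", "phi_psii", "ppfd")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("records missing column(s): ", paste(miss, collapse = ", "))
  m <- colMeans(records[, req, drop = FALSE], na.rm = TRUE)
  if (!is.finite(m[["pn"]]) || m[["pn"]] <= 0) return(NA_real_)
  j <- electron_transport_rate(m[["phi_psii"]], m[["ppfd"]],
                               constants$absorptance, constants$psii_fraction)
  if (j <= 4 * (m[["pn"]] + rd)) return(NA_real_)
  out <- suppressWarnings(
    variable_j_gm(m[["pn"]], m[["ci_umol_mol"]], j, rd, gamma_star))
  unname(out)
}

#' Append derived diffusion quantities to gas-exchange records
#'
#' Per-record pipeline step: computes gsc from gsw, J from fluorescence,
#' the variable-J gm, gtot, Cc and the transport ratios, with a validity
#' flag. Records with non-positive Pn, inconsistent J, or a non-positive
#' variable-J denominator get `gm_valid = FALSE` and `NA` derived values
#' (never silently dropped). If the records carry a `limitation` column and
#' `screen_rubisco = TRUE`, Rubisco-limited records are also flagged
#' invalid, reflecting the estimator's RuBP-regeneration derivation.
#'
#' @param records Gas-exchange data.frame with columns `pn`, `gsw`,
#'   `ci_umol_mol`, `phi_psii`, `ppfd`, `ca_umol_mol`.
#' @param rd,gamma_star Day respiration (umol m-2 s-1) and
#'   photocompensation point (umol mol-1) used by the estimator.
#' @param screen_rubisco Flag Rubisco-limited records invalid when a
#'   `limitation` column is present.
#' @param constants [photo_constants()].
#' @return The input data.frame with appended columns `gsc`, `j`, `gm`,
#'   `gtot`, `cc_umol_mol`, `ci_over_ca`, `cc_over_ca`, `cc_over_ci`,
#'   `gm_valid`.
#' @export
derive_conductances <- function(records, rd, gamma_star,
                                screen_rubisco = FALSE,
                                constants = photo_constants()) {
  req <- c("pn", "gsw", "ci_umol_mol", "phi_psii", "ppfd", "ca_umol_mol")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("records missing column(s): ", paste(miss, collapse = ", "))
  records$gsc <- records$gsw / constants$diffusivity_ratio
  records$j <- electron_transport_rate(records$phi_psii, records$ppfd,
                                       constants$absorptance,
                                       constants$psii_fraction)
  ok <- records$pn > 0 & records$j > 4 * (records$pn + rd)
  if (screen_rubisco && "limitation" %in% names(records)) {
    ok <- ok & records$limitation != "rubisco"
  }
  gm <- rep(NA_real_, nrow(records))
  if (any(ok)) {
    gm[ok] <- suppressWarnings(
      variable_j_gm(records$pn[ok], records$ci_umol_mol[ok], records$j[ok],
                    rd, gamma_star)
    )
  }
  records$gm <- gm
  records$gm_valid <- !is.na(gm)
  records$gtot <- ifelse(records$gm_valid,
                         total_conductance(records$gsc, ifelse(is.na(gm), 1, gm)),
                         NA_real_)
  records$cc_umol_mol <- ifelse(records$gm_valid,
                                chloroplast_co2(records$pn, records$ci_umol_mol,
                                                ifelse(is.na(gm), 1, gm)),
                                NA_real_)
  rat <- transport_ratios(records$ca_umol_mol,
                          pmax(records$ci_umol_mol, .Machine$double.eps),
                          pmax(ifelse(is.na(records$cc_umol_mol), 1,
                                      records$cc_umol_mol), .Machine$double.eps))
  records$ci_over_ca <- rat$ci_over_ca
  records$cc_over_ca <- ifelse(records$gm_valid, rat$cc_over_ca, NA_real_)
  records$cc_over_ci <- ifelse(records$gm_valid, rat$cc_over_ci, NA_real_)
  n_bad <- sum(!records$gm_valid)
  if (n_bad) {
    message(n_bad, " of ", nrow(records),
            " record(s) flagged invalid for variable-J gm estimation")
  }
  records
}
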