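#' Electron transport light response
#'
#' Potential electron transport rate from the non-rectangular hyperbola
#' light response: the lower root of
#' `theta J^2 - (alpha PPFD + Jmax) J + alpha PPFD Jmax = 0`.
#'
#' @param ppfd Photon flux density, umol m-2 s-1 (vectorised).
#' @param jmax Maximum electron transport rate, umol m-2 s-1.
#' @param alpha Apparent quantum yield, mol e- per mol photons.
#' @param theta Curvature parameter in (0, 1].
#' @return Electron transport rate J, umol m-2 s-1.
#' @export
#' @examples
#' j_light_response(1100, jmax = 140)
j_light_response <- function(ppfd, jmax, alpha = 0.3, theta = 0.9) {
  stopifnot(all(ppfd >= 0), jmax > 0, alpha > 0, theta > 0, theta <= 1)
  q <- alpha * ppfd
  (q + jmax - sqrt((q + jmax)^2 - 4 * theta * q * jmax)) / (2 * theta)
}

#' FvCB assimilation rates at a chloroplastic CO2 mole fraction
#'
#' Rubisco-limited (`ac`) and RuBP-regeneration-limited (`aj`) gross
#' carboxylation rates and the net rate `a_net = min(ac, aj) - rd`,
#' evaluated at chloroplastic CO2 `cc`. The transition between the two
#' states is a hard minimum (no hyperbolic smoothing), which keeps the
#' limitation-partition derivative analytically tractable.
#'
#' @param cc Chloroplastic CO2 mole fraction, umol mol-1 (vectorised).
#' @param params [leaf_phys_params()] object.
#' @param ppfd Photon flux density, umol m-2 s-1 (used for J); a
#'   pre-computed `j` may be supplied instead.
#' @param j Optional electron transport rate overriding the light response.
#' @return A data.frame with columns `cc`, `ac`, `aj`, `a_net` and
#'   `limitation` (`"rubisco"` or `"rubp"`).
#' @export
#' @examples
#' fvcb_rates(c(100, 300), leaf_phys_params(), ppfd = 1100)
fvcb_rates <- function(cc, params, ppfd = NULL, j = NULL) {
  stopifnot(inherits(params, "leaf_phys_params"))
  if (is.null(j)) {
    if (is.null(ppfd)) stop("supply either ppfd or j")
    j <- j_light_response(ppfd, params$jmax, params$alpha_j, params$theta_j)
  }
  km <- params$kc * (1 + params$o2 / params$ko)
  ac <- params$vcmax * (cc - params$gamma_star) / (cc + km)
  aj <- j * (cc - params$gamma_star) / (4 * cc + 8 * params$gamma_star)
  gross <- pmin(ac, aj)
  data.frame(cc = cc, ac = ac, aj = aj, a_net = gross - params$rd,
             limitation = ifelse(ac <= aj, "rubisco", "rubp"),
             stringsAsFactors = FALSE)
}

#' Solve the steady-state supply-demand balance of a leaf
#'
#' Finds the unique chloroplastic CO2 mole fraction at which the diffusive
#' CO2 supply through the stomatal + mesophyll series circuit,
#' `gtot (Ca - Cc)`, equals the FvCB biochemical demand
#' `min(Ac, Aj) - Rd`. Intercellular CO2 is back-computed from Fick's law
#' across the stomata, and the PSII operating efficiency is back-computed
#' from the actual electron transport rate
#' `J = (Pn + Rd)(4 Cc + 8 Gamma*)/(Cc - Gamma*)` so that the
#' fluorescence-based estimator [electron_transport_rate()] reproduces it
#' exactly (this equals the light-response J on RuBP-limited points and is
#' smaller under Rubisco limitation, as measured fluorescence would be).
#'
#' @param params [leaf_phys_params()].
#' @param gsc Stomatal conductance to CO2, mol m-2 s-1.
#' @param gm Mesophyll conductance, mol m-2 s-1.
#' @param env [environment_state()].
#' @param constants Output of [photo_constants()].
#' @return A one-row data.frame (a gas-exchange record) with columns
#'   `vpd_kpa`, `t_leaf_c`, `ppfd`, `ca_umol_mol`, `o2_mmol_mol`, `pn`,
#'   `gsw`, `ci_umol_mol`, `phi_psii`, `j_flu`, `cc_true`, `limitation`.
#' @export
#' @examples
#' solve_steady_state(leaf_phys_params(), gsc = 0.25, gm = 0.3,
#'                    environment_state())
solve_steady_state <- function(params, gsc, gm, env,
                               constants = photo_constants()) {
  stopifnot(inherits(params, "leaf_phys_params"),
            inherits(env, "environment_state"))
  if (!is.numeric(gsc) || gsc <= 0 || !is.numeric(gm) || gm <= 0) {
    stop("gsc and gm must be strictly positive")
  }
  gtot <- 1 / (1 / gsc + 1 / gm)
  ca <- env$ca
  j_pot <- j_light_response(env$ppfd, params$jmax, params$alpha_j,
                            params$theta_j)
  f <- function(cc) {
    gtot * (ca - cc) -
      fvcb_rates(cc, params, j = j_pot)$a_net
  }
  lo <- 1e-9
  hi <- ca + params$rd / gtot + 50
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    stop("no supply-demand sign change in (0, Ca + Rd/gtot]: ",
         "non-physical parameter combination")
  }
  cc <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  if (cc <= 0) stop("negative chloroplastic CO2 root rejected")
  rates <- fvcb_rates(cc, params, j = j_pot)
  pn <- rates$a_net
  ci <- ca - pn / gsc
  gross <- pn + params$rd
  # Actual electron flux consistent with achieved carboxylation.
  if (abs(cc - params$gamma_star) < 1e-8 || env$ppfd == 0) {
    j_act <- if (env$ppfd == 0) 0 else j_pot
  } else {
    j_act <- gross * (4 * cc + 8 * params$gamma_star) /
      (cc - params$gamma_star)
  }
  phi <- if (env$ppfd > 0) {
    j_act / (env$ppfd * constants$absorptance * constants$psii_fraction)
  } else 0
  data.frame(
    vpd_kpa = env$vpd, t_leaf_c = env$t_leaf, ppfd = env$ppfd,
    ca_umol_mol = ca, o2_mmol_mol = env$o2,
    pn = pn, gsw = gsc * constants$diffusivity_ratio,
    ci_umol_mol = ci, phi_psii = phi, j_flu = j_act,
    cc_true = cc, limitation = rates$limitation,
    stringsAsFactors = FALSE
  )
}
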