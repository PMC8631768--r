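#' @keywords internal
#' Run fn with a locally-set RNG seed, restoring global state afterwards.
with_local_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' @keywords internal
#' Multiplicative Gaussian observation noise on pn and gsw; ci recomputed
#' from the noisy observables so each record stays internally consistent.
apply_obs_noise <- function(records, noise_cv, constants = photo_constants()) {
  cv_pn <- noise_cv[["pn"]]
  cv_gsw <- noise_cv[["gsw"]]
  n <- nrow(records)
  if (cv_pn > 0) records$pn <- records$pn * (1 + cv_pn * stats::rnorm(n))
  if (cv_gsw > 0) records$gsw <- records$gsw * (1 + cv_gsw * stats::rnorm(n))
  gsc <- records$gsw / constants$diffusivity_ratio
  records$ci_umol_mol <- records$ca_umol_mol - records$pn / gsc
  records
}

#' Simulate an A-Ci response curve
#'
#' Forward-simulates a steady-state CO2 response at fixed light and
#' conductances, following the standard measurement protocol: ambient CO2
#' stepped down 400, 300, 200, 150, 100, 50 umol mol-1, returned to 400,
#' then stepped up to 1200 umol mol-1.
#'
#' @param params [leaf_phys_params()].
#' @param gsc,gm Stomatal (CO2 basis) and mesophyll conductance,
#'   mol m-2 s-1, held constant along the curve.
#' @param env [environment_state()]; its `ca` is ignored in favour of the
#'   protocol values, and `ppfd` may be overridden via `light`.
#' @param light Optional PPFD override, umol m-2 s-1.
#' @param ca_protocol Optional explicit Ca sequence; default is the standard
#'   protocol with ascending step `ascending_step`.
#' @param ascending_step Step size of the ascending limb, umol mol-1.
#' @param noise_cv Named numeric `c(pn=, gsw=)` multiplicative observation
#'   noise CVs; 0 disables noise.
#' @param seed Optional RNG seed for the noise (global RNG state restored).
#' @return A data.frame of gas-exchange records (see
#'   [solve_steady_state()]) in protocol order.
#' @export
#' @examples
#' curve <- generate_aci_curve(leaf_phys_params(), 0.25, 0.3,
#'                             environment_state())
#' nrow(curve)  # 11 records under the default protocol
generate_aci_curve <- function(params, gsc, gm, env, light = NULL,
                               ca_protocol = NULL, ascending_step = 200,
                               noise_cv = c(pn = 0, gsw = 0), seed = NULL) {
  if (!is.null(light)) {
    if (light < 0) stop("light must be >= 0")
    env$ppfd <- light
  }
  if (is.null(ca_protocol)) {
    ca_protocol <- c(400, 300, 200, 150, 100, 50, 400,
                     seq(400 + ascending_step, 1200, by = ascending_step))
  }
  rows <- lapply(ca_protocol, function(ca) {
    e <- env
    e$ca <- ca
    solve_steady_state(params, gsc, gm, e)
  })
  out <- do.call(rbind, rows)
  out$step <- seq_len(nrow(out))
  with_local_seed(seed, function() apply_obs_noise(out, noise_cv))
}

#' Simulate a two-light low-CO2 dataset for the Laisk procedure
#'
#' Generates steady-state records on a low-CO2 grid at two light
#' intensities (defaults 75 and 500 umol m-2 s-1, Ca 30-120 umol mol-1),
#' the inputs of [laisk_intersection()].
#'
#' @inheritParams generate_aci_curve
#' @param ca_grid Ambient CO2 grid, umol mol-1.
#' @param lights Two PPFD levels, umol m-2 s-1.
#' @return A data.frame of records with a `light_level` column.
#' @export
#' @examples
#' d <- generate_laisk_dataset(leaf_phys_params(), 0.25, 10,
#'                             environment_state())
#' table(d$light_level)
generate_laisk_dataset <- function(params, gsc, gm, env,
                                   ca_grid = c(30, 60, 90, 120),
                                   lights = c(75, 500),
                                   noise_cv = c(pn = 0, gsw = 0),
                                   seed = NULL) {
  stopifnot(length(lights) == 2L)
  rows <- lapply(lights, function(ll) {
    d <- lapply(ca_grid, function(ca) {
      e <- env
      e$ca <- ca
      e$ppfd <- ll
      solve_steady_state(params, gsc, gm, e)
    })
    d <- do.call(rbind, d)
    d$light_level <- ll
    d
  })
  out <- do.call(rbind, rows)
  with_local_seed(seed, function() apply_obs_noise(out, noise_cv))
}

#' Simulate a steady-state VPD-response study
#'
#' For each VPD level of the grid, conductances follow the linear declines
#' of the response parameter set (`gsw = gs_slope VPD + gs_intercept`,
#' likewise `gm`; `gsc = gsw / 1.6`), the steady state is solved under the
#' standard environment, foliar ABA rises exponentially and leaf water
#' potential declines linearly. Replicates differ only through the
#' multiplicative observation noise; with `noise = FALSE` they are
#' identical.
#'
#' @param params [leaf_phys_params()].
#' @param resp [vpd_response_params()].
#' @param vpd_grid VPD levels, kPa; conductance predictions must stay
#'   positive over the grid.
#' @param n_rep Replicates per VPD level.
#' @param env Base [environment_state()]; its `vpd` is replaced per level.
#' @param noise Logical; apply the `resp$noise_cv` observation noise.
#' @param seed Optional RNG seed (global RNG state restored); the dataset is
#'   bit-reproducible given the same seed.
#' @return A data.frame with one row per (VPD, replicate): gas-exchange
#'   record columns plus `sample_id`, `regime`, `cultivar`, `rep`,
#'   `gsc_true`, `gm_true`, `aba_ng_g`, `psi_leaf_mpa`, `psi_soil_mpa`,
#'   `lma_g_m2`.
#' @export
#' @examples
#' d <- simulate_vpd_response(leaf_phys_params(), vpd_response_params("LVPD"),
#'                            noise = FALSE)
#' d[d$rep == 1, c("vpd_kpa", "pn", "gsw", "aba_ng_g")]
simulate_vpd_response <- function(params, resp,
                                  vpd_grid = c(0.5, 1.5, 2.5, 3.5, 4.5),
                                  n_rep = 4, env = environment_state(),
                                  noise = TRUE, seed = NULL) {
  stopifnot(inherits(resp, "vpd_response_params"))
  constants <- photo_constants()
  gsw <- resp$gs_slope * vpd_grid + resp$gs_intercept
  gmv <- resp$gm_slope * vpd_grid + resp$gm_intercept
  if (any(gsw <= 0) || any(gmv <= 0)) {
    bad <- vpd_grid[gsw <= 0 | gmv <= 0]
    stop("predicted conductance non-positive at VPD ",
         paste(bad, collapse = ", "), " kPa; narrow the grid")
  }
  base_rows <- lapply(seq_along(vpd_grid), function(i) {
    e <- env
    e$vpd <- vpd_grid[i]
    rec <- solve_steady_state(params, gsw[i] / constants$diffusivity_ratio,
                              gmv[i], e)
    rec$gsc_true <- gsw[i] / constants$diffusivity_ratio
    rec$gm_true <- gmv[i]
    rec$aba_ng_g <- resp$aba_scale * exp(resp$aba_rate * vpd_grid[i])
    rec$psi_leaf_mpa <- resp$psi_leaf_slope * vpd_grid[i] +
      resp$psi_leaf_intercept
    rec$psi_soil_mpa <- resp$psi_soil
    rec$lma_g_m2 <- resp$lma
    rec
  })
  base <- do.call(rbind, base_rows)
  out <- base[rep(seq_len(nrow(base)), each = n_rep), , drop = FALSE]
  out$rep <- rep(seq_len(n_rep), times = nrow(base))
  out$regime <- resp$regime
  out$cultivar <- resp$cultivar
  out$sample_id <- sprintf("%s_%s_v%03.1f_r%d", resp$regime, resp$cultivar,
                           out$vpd_kpa, out$rep)
  rownames(out) <- NULL
  if (noise) {
    with_local_seed(seed, function() apply_obs_noise(out, resp$noise_cv))
  } else {
    out
  }
}
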