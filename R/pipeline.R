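#' Build and validate a pipeline configuration
#'
#' Assembles the configuration consumed by [run_pipeline()]: physical
#' constants, FvCB physiology, per-regime VPD-response parameter sets,
#' measurement protocol (VPD grid, replicate count, A-Ci protocol, low-CO2
#' ramp for the dA/dCc window, Laisk grid), noise switches, seed and output
#' precision. Defaults reproduce the bundled two-regime synthetic study.
#'
#' @param physiology Named list of [leaf_phys_params()] arguments.
#' @param regimes Character vector of growth regimes to simulate.
#' @param cultivar Cultivar label.
#' @param vpd_grid VPD levels, kPa (all >= 0).
#' @param n_rep Replicates per VPD level.
#' @param slope_ca_grid Ambient CO2 grid of the low-CO2 ramp used for the
#'   dA/dCc slope, umol mol-1.
#' @param laisk_ca_grid,laisk_lights Laisk protocol (Ca grid, two PPFDs).
#' @param aci_step Ascending-limb step of the A-Ci protocol, umol mol-1.
#' @param env Named list of [environment_state()] arguments (base
#'   environment; VPD and Ca are set per measurement) plus `t_air`, the air
#'   temperature used for air water potential. `t_air` must be warm enough
#'   that the highest VPD of the grid stays below saturation vapour
#'   pressure (a leaf at 28 C can face a 4.5 kPa VPD only in warmer air).
#' @param noise Logical: apply observation noise in the simulate stage.
#' @param noise_cv Named `c(pn=, gsw=)` CVs.
#' @param seed Integer seed for the simulate stage.
#' @param digits Significant digits of written tables.
#' @return A validated config list of class `"pipeline_config"`.
#' @export
#' @examples
#' cfg <- pipeline_config(noise = FALSE)
pipeline_config <- function(physiology = list(),
                            regimes = c("HVPD", "LVPD"),
                            cultivar = "CV1",
                            vpd_grid = c(0.5, 1.5, 2.5, 3.5, 4.5),
                            n_rep = 4,
                            slope_ca_grid = c(50, 75, 100, 125, 150),
                            laisk_ca_grid = c(30, 60, 90, 120),
                            laisk_lights = c(75, 500),
                            aci_step = 200,
                            env = list(t_leaf = 28, ppfd = 1100, ca = 400,
                                       o2 = 210, t_air = 32),
                            noise = TRUE,
                            noise_cv = c(pn = 0.02, gsw = 0.05),
                            seed = 1L,
                            digits = 6) {
  if (any(vpd_grid < 0)) stop("config invalid: negative VPD in vpd_grid")
  if (n_rep < 1) stop("config invalid: n_rep must be >= 1")
  if (length(laisk_lights) != 2L) stop("config invalid: need two Laisk lights")
  if (!is.numeric(seed) || length(seed) != 1L) {
    stop("config invalid: seed must be a single integer")
  }
  params <- do.call(leaf_phys_params, physiology)
  resp <- lapply(regimes, function(rg) {
    vpd_response_params(rg, cultivar = cultivar, noise_cv = noise_cv)
  })
  names(resp) <- regimes
  structure(list(
    params = params, resp = resp, regimes = regimes, cultivar = cultivar,
    vpd_grid = vpd_grid, n_rep = n_rep, slope_ca_grid = slope_ca_grid,
    laisk_ca_grid = laisk_ca_grid, laisk_lights = laisk_lights,
    aci_step = aci_step, env = env, noise = noise, noise_cv = noise_cv,
    seed = as.integer(seed), digits = digits
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; absent keys take the
#' documented defaults.
#'
#' @param path YAML file path.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(y$noise_cv)) y$noise_cv <- unlist(y$noise_cv)
  do.call(pipeline_config, y)
}

#' @keywords internal
base_env_from_config <- function(config, vpd = 1.5) {
  args <- config$env[intersect(names(config$env),
                               setdiff(names(formals(environment_state)), "vpd"))]
  do.call(environment_state, c(list(vpd = vpd), args))
}

#' Run the full VPD limitation-analysis pipeline
#'
#' Chains the stages simulate -> diffusion -> fitting -> partition ->
#' water -> regressions on the configured synthetic study, returning a
#' result bundle and optionally persisting every table as TSV plus a JSON
#' run manifest (package/R versions, seed, config hash, per-stage record
#' counts). Reruns with an identical config and seed write byte-identical
#' tables. A stage failure aborts with the stage name after persisting the
#' completed stages and the manifest.
#'
#' The diffusion stage first performs the Laisk two-light estimation of Rd
#' and Gamma* (inputs of the variable-J estimator) and then derives
#' per-record conductances; the fitting stage fits CE and FvCB capacities
#' per regime and VPD level on the Cc axis using the level's mean
#' variable-J gm.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for TSV tables and
#'   `manifest.json`.
#' @return A list of class `"vpdlim_bundle"` with elements `gas_exchange`,
#'   `laisk`, `conductances`, `capacity`, `partitions`, `partition_trends`,
#'   `water`, `regressions` and `manifest`.
#' @export
#' @examples
#' \donttest{
#' bundle <- run_pipeline(pipeline_config(noise = FALSE))
#' bundle$partitions
#' }
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  bundle <- list()
  manifest <- list(
    package = "vpdlim",
    package_version = as.character(utils::packageVersion("vpdlim")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    stages = list()
  )
  persist <- function() {
    if (is.null(out_dir)) return(invisible(NULL))
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in names(bundle)) {
      if (is.data.frame(bundle[[nm]])) {
        write_result_table(bundle[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                           config$digits)
      }
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(NULL)
  }
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      bundle$manifest <<- manifest
      persist()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    res
  }
  cv0 <- c(pn = 0, gsw = 0)
  cv <- if (config$noise) config$noise_cv else cv0

  ## --- stage 1: simulate ---------------------------------------------------
  sim <- run_stage("simulate", function() {
    steady <- lapply(config$regimes, function(rg) {
      simulate_vpd_response(config$params, config$resp[[rg]],
                            vpd_grid = config$vpd_grid, n_rep = config$n_rep,
                            env = base_env_from_config(config),
                            noise = config$noise, seed = config$seed)
    })
    steady <- do.call(rbind, steady)
    curves <- list(); ramps <- list(); laisk <- list()
    k <- 0L
    for (rg in config$regimes) {
      resp <- config$resp[[rg]]
      for (vpd in config$vpd_grid) {
        k <- k + 1L
        gsw <- resp$gs_slope * vpd + resp$gs_intercept
        gmv <- resp$gm_slope * vpd + resp$gm_intercept
        gsc <- stomatal_conductance_co2(gsw)
        env <- base_env_from_config(config, vpd = vpd)
        cu <- generate_aci_curve(config$params, gsc, gmv, env,
                                 ascending_step = config$aci_step,
                                 noise_cv = cv, seed = config$seed + k)
        cu$regime <- rg; cu$curve <- "aci"
        ra <- generate_aci_curve(config$params, gsc, gmv, env,
                                 ca_protocol = config$slope_ca_grid,
                                 noise_cv = cv, seed = config$seed + 1000L + k)
        ra$regime <- rg; ra$curve <- "ramp"
        curves[[k]] <- cu; ramps[[k]] <- ra
      }
      vpd0 <- config$vpd_grid[1]
      gsw0 <- resp$gs_slope * vpd0 + resp$gs_intercept
      gmv0 <- resp$gm_slope * vpd0 + resp$gm_intercept
      la <- generate_laisk_dataset(config$params,
                                   stomatal_conductance_co2(gsw0), gmv0,
                                   base_env_from_config(config, vpd = vpd0),
                                   ca_grid = config$laisk_ca_grid,
                                   lights = config$laisk_lights,
                                   noise_cv = cv,
                                   seed = config$seed + 2000L + match(rg, config$regimes))
      la$regime <- rg
      laisk[[rg]] <- la
    }
    list(steady = steady, curves = do.call(rbind, c(curves, ramps)),
         laisk = do.call(rbind, laisk))
  })
  bundle$gas_exchange <- sim$steady
  bundle$aci_curves <- sim$curves
  bundle$laisk_data <- sim$laisk
  manifest$stages$simulate <- list(status = "ok",
                                   n_records = nrow(sim$steady) +
                                     nrow(sim$curves) + nrow(sim$laisk))

  ## --- stage 2: diffusion (Laisk inputs + conductance derivation) ----------
  diff <- run_stage("diffusion", function() {
    laisk_fits <- lapply(config$regimes, function(rg) {
      d <- sim$laisk[sim$laisk$regime == rg, ]
      lo <- d[d$light_level == min(d$light_level), ]
      hi <- d[d$light_level == max(d$light_level), ]
      est <- laisk_intersection(lo, hi)
      data.frame(regime = rg, gamma_star = est$gamma_star, rd = est$rd,
                 stringsAsFactors = FALSE)
    })
    laisk_fits <- do.call(rbind, laisk_fits)
    cond <- lapply(config$regimes, function(rg) {
      lf <- laisk_fits[laisk_fits$regime == rg, ]
      d <- sim$steady[sim$steady$regime == rg, ]
      suppressMessages(derive_conductances(d, rd = lf$rd,
                                           gamma_star = lf$gamma_star))
    })
    list(laisk_fits = laisk_fits, cond = do.call(rbind, cond))
  })
  bundle$laisk <- diff$laisk_fits
  bundle$conductances <- diff$cond
  manifest$stages$diffusion <- list(
    status = "ok", n_records = nrow(diff$cond),
    n_invalid_gm = sum(!diff$cond$gm_valid))

  ## --- stage 3: fitting (CE + FvCB capacities per regime x VPD) ------------
  capacity <- run_stage("fitting", function() {
    rows <- list(); k <- 0L
    for (rg in config$regimes) {
      lf <- bundle$laisk[bundle$laisk$regime == rg, ]
      for (vpd in config$vpd_grid) {
        k <- k + 1L
        cu <- sim$curves[sim$curves$regime == rg & sim$curves$curve == "aci" &
                           sim$curves$vpd_kpa == vpd, ]
        ce <- fit_ce(cu)
        d <- bundle$conductances[bundle$conductances$regime == rg &
                                   bundle$conductances$vpd_kpa == vpd, ]
        gm_hat <- gm_from_replicates(d[d$gm_valid, , drop = FALSE],
                                     rd = lf$rd, gamma_star = lf$gamma_star)
        if (is.finite(gm_hat)) {
          cu$cc_umol_mol <- chloroplast_co2(cu$pn, cu$ci_umol_mol, gm_hat)
        }
        fv <- suppressWarnings(
          fit_fvcb(cu[, setdiff(names(cu), "cc_true")],
                   rd = lf$rd, gamma_star = lf$gamma_star,
                   kc = config$params$kc, ko = config$params$ko,
                   o2 = config$params$o2, alpha = config$params$alpha_j,
                   theta = config$params$theta_j))
        rows[[k]] <- data.frame(
          regime = rg, cultivar = config$cultivar, vpd_kpa = vpd,
          ce = ce$ce, ce_r2 = ce$r2,
          vcmax = if (fv$converged) fv$vcmax else NA_real_,
          jmax = if (fv$converged) fv$jmax else NA_real_,
          gm_hat = gm_hat, axis = fv$axis,
          rmse = if (fv$converged) fv$rmse else NA_real_,
          r2 = if (fv$converged) fv$r2 else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  bundle$capacity <- capacity
  manifest$stages$fitting <- list(status = "ok", n_records = nrow(capacity))

  ## --- stage 4: partition --------------------------------------------------
  part <- run_stage("partition", function() {
    rows <- list(); k <- 0L
    for (rg in config$regimes) {
      for (vpd in config$vpd_grid) {
        k <- k + 1L
        d <- bundle$conductances[bundle$conductances$regime == rg &
                                   bundle$conductances$vpd_kpa == vpd, ]
        lf <- bundle$laisk[bundle$laisk$regime == rg, ]
        gsc <- mean(d$gsc)
        gm_hat <- gm_from_replicates(d[d$gm_valid, , drop = FALSE],
                                     rd = lf$rd, gamma_star = lf$gamma_star)
        ra <- sim$curves[sim$curves$regime == rg & sim$curves$curve == "ramp" &
                           sim$curves$vpd_kpa == vpd, ]
        if (is.finite(gm_hat)) {
          ra$cc_umol_mol <- chloroplast_co2(ra$pn, ra$ci_umol_mol, gm_hat)
          k_slope <- tryCatch(da_dcc_slope(ra[, setdiff(names(ra), "cc_true")]),
                              error = function(e) NA_real_)
        } else {
          k_slope <- NA_real_
        }
        rows[[k]] <- data.frame(vpd = vpd, regime = rg,
                                cultivar = config$cultivar,
                                gsc = gsc, gm = gm_hat, da_dcc = k_slope,
                                stringsAsFactors = FALSE)
      }
    }
    prof <- do.call(rbind, rows)
    ok <- stats::complete.cases(prof[, c("gsc", "gm", "da_dcc")])
    if (sum(!ok)) {
      message(sum(!ok), " VPD level(s) without valid gm/slope excluded ",
              "from the partition")
    }
    partition_profile(prof[ok, , drop = FALSE])
  })
  bundle$partitions <- as.data.frame(part$partitions)
  bundle$partition_trends <- part$trends
  manifest$stages$partition <- list(status = "ok",
                                    n_records = nrow(bundle$partitions))

  ## --- stage 5: water ------------------------------------------------------
  water <- run_stage("water", function() {
    agg <- stats::aggregate(
      cbind(psi_leaf_mpa, psi_soil_mpa) ~ regime + vpd_kpa,
      data = bundle$gas_exchange, FUN = mean)
    t_air <- config$env$t_air %||% config$env$t_leaf
    psi_air <- air_water_potential(agg$vpd_kpa, t_air = t_air)
    df <- driving_forces(agg$psi_soil_mpa, agg$psi_leaf_mpa, psi_air,
                         vpd = agg$vpd_kpa, t_air = t_air)
    df$regime <- agg$regime
    df
  })
  bundle$water <- water
  manifest$stages$water <- list(status = "ok", n_records = nrow(water))

  ## --- stage 6: regressions ------------------------------------------------
  regressions <- run_stage("regressions", function() {
    rows <- list(); k <- 0L
    add <- function(regime, response, fit) {
      k <<- k + 1L
      rows[[k]] <<- data.frame(
        regime = regime, response = response, form = fit$form,
        p1 = unname(fit$params[1]), p2 = unname(fit$params[2]),
        r2 = fit$r2, n = fit$n, stringsAsFactors = FALSE)
    }
    for (rg in config$regimes) {
      d <- bundle$conductances[bundle$conductances$regime == rg, ]
      v <- d$vpd_kpa
      add(rg, "gsw", fit_response(v, d$gsw, "linear", c("VPD", "gsw")))
      ok <- d$gm_valid
      add(rg, "gm", fit_response(v[ok], d$gm[ok], "linear", c("VPD", "gm")))
      add(rg, "gtot", fit_response(v[ok], d$gtot[ok], "linear", c("VPD", "gtot")))
      add(rg, "ci", fit_response(v, d$ci_umol_mol, "linear", c("VPD", "Ci")))
      add(rg, "cc", fit_response(v[ok], d$cc_umol_mol[ok], "linear",
                                 c("VPD", "Cc")))
      add(rg, "aba", fit_response(v, d$aba_ng_g, "exponential",
                                  c("VPD", "ABA")))
      add(rg, "psi_leaf", fit_response(v, d$psi_leaf_mpa, "linear",
                                       c("VPD", "Psi_leaf")))
      add(rg, "gs_vs_aba", fit_response(d$aba_ng_g, d$gsw, "linear",
                                        c("ABA", "gsw")))
      add(rg, "gm_vs_aba", fit_response(d$aba_ng_g[ok], d$gm[ok], "linear",
                                        c("ABA", "gm")))
      w <- bundle$water[bundle$water$regime == rg &
                          is.finite(bundle$water$ratio_leaf_air_to_soil_leaf), ]
      if (nrow(w) >= 3) {
        add(rg, "driving_force_ratio",
            fit_response(w$vpd, w$ratio_leaf_air_to_soil_leaf, "logarithmic",
                         c("VPD", "ratio")))
      }
    }
    do.call(rbind, rows)
  })
  bundle$regressions <- regressions
  manifest$stages$regressions <- list(status = "ok",
                                      n_records = nrow(regressions))

  bundle$manifest <- manifest
  persist()
  structure(bundle, class = c("vpdlim_bundle", "list"))
}

#' Human-readable summary of a pipeline result bundle
#'
#' Formats per-regime tables of conductance, capacity, limitation
#' partition, water status and regression coefficients in the style of
#' figure captions. Regenerating the report from a persisted bundle yields
#' identical text.
#'
#' @param bundle A `"vpdlim_bundle"` from [run_pipeline()].
#' @return Character vector of report lines, invisibly; printed to the
#'   console.
#' @export
emit_report <- function(bundle) {
  ln <- character()
  push <- function(...) ln <<- c(ln, sprintf(...))
  push("== VPD limitation analysis report ==")
  push("seed %d, config %s", bundle$manifest$seed, bundle$manifest$config_hash)
  push("")
  push("-- Laisk estimates --")
  for (i in seq_len(nrow(bundle$laisk))) {
    push("%s: Gamma* = %.2f umol mol-1, Rd = %.2f umol m-2 s-1",
         bundle$laisk$regime[i], bundle$laisk$gamma_star[i], bundle$laisk$rd[i])
  }
  push("")
  push("-- Limitation partition --")
  if (nrow(bundle$partitions) == 0) {
    push("no valid records")
  } else {
    for (i in seq_len(nrow(bundle$partitions))) {
      p <- bundle$partitions[i, ]
      push("%s VPD %.1f kPa: Ls = %.3f, Lm = %.3f, Lb = %.3f (dA/dCc = %.4f)",
           p$regime, p$vpd, p$ls, p$lm, p$lb, p$da_dcc)
    }
  }
  push("")
  push("-- Regression summary --")
  if (is.null(bundle$regressions) || nrow(bundle$regressions) == 0) {
    push("no valid records")
  } else {
    for (i in seq_len(nrow(bundle$regressions))) {
      r <- bundle$regressions[i, ]
      eq <- switch(r$form,
        linear = sprintf("%s = %.4g x + %.4g", r$response, r$p1, r$p2),
        logarithmic = sprintf("%s = %.4g ln(x) + %.4g", r$response, r$p1, r$p2),
        exponential = sprintf("%s = %.4g e^(%.4g x)", r$response, r$p1, r$p2))
      push("%s: %s, R2 = %.2f (n = %d)", r$regime, eq, r$r2, r$n)
    }
  }
  cat(paste(ln, collapse = "\n"), "\n")
  invisible(ln)
}
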