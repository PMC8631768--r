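#' Slope of the Pn-Cc response in the low-CO2 window
#'
#' Ordinary least-squares slope of net photosynthesis on chloroplastic CO2
#' over the window `cc` in `[40, 110]` umol mol-1, the carboxylation-rate
#' proxy `dA/dCc` used by the limitation partition. The window is applied
#' on the Cc axis (the variable being differentiated); points outside it
#' are ignored.
#'
#' @param curve Data.frame with columns `pn` and `cc_umol_mol` (or
#'   `cc_true`).
#' @param window Numeric `c(min, max)` Cc window, umol mol-1.
#' @return Slope, mol m-2 s-1.
#' @export
#' @examples
#' curve <- generate_aci_curve(leaf_phys_params(), 0.25, 0.3,
#'                             environment_state(),
#'                             ca_protocol = c(50, 75, 100, 125, 150))
#' curve$cc_umol_mol <- curve$cc_true
#' da_dcc_slope(curve)
da_dcc_slope <- function(curve, window = c(40, 110)) {
  cc_col <- intersect(c("cc_umol_mol", "cc_true"), names(curve))
  if (!length(cc_col)) stop("curve must carry a cc_umol_mol or cc_true column")
  cc <- curve[[cc_col[1]]]
  keep <- is.finite(cc) & cc >= window[1] & cc <= window[2]
  if (sum(keep) < 3) {
    stop("need >= 3 points with Cc in [", window[1], ", ", window[2],
         "] umol mol-1 (got ", sum(keep), ")")
  }
  fit <- stats::lm(pn ~ cc, data = data.frame(pn = curve$pn[keep], cc = cc[keep]))
  unname(stats::coef(fit)[2])
}

#' Partition photosynthetic limitation into stomatal, mesophyll and
#' biochemical fractions
#'
#' With `k = dA/dCc` and `gtot` the series combination of `gsc` and `gm`:
#' \deqn{L_s = (g_{tot}/g_{sc}) k / (g_{tot} + k), \quad
#'       L_m = (g_{tot}/g_m) k / (g_{tot} + k), \quad
#'       L_b = g_{tot} / (g_{tot} + k)}
#' The three fractions sum to one exactly by construction.
#'
#' @param gsc Stomatal conductance to CO2, mol m-2 s-1 (vectorised).
#' @param gm Mesophyll conductance, mol m-2 s-1.
#' @param da_dcc Slope of Pn on Cc, mol m-2 s-1.
#' @param vpd Optional VPD label, kPa.
#' @param regime,cultivar Optional labels carried through.
#' @return Data.frame of class `"limitation_partition"` with columns `vpd`,
#'   `regime`, `cultivar`, `ls`, `lm`, `lb`, `da_dcc`, `gsc`, `gm`, `gtot`.
#' @export
#' @examples
#' partition(gsc = 0.2, gm = 0.2, da_dcc = 0.1)
partition <- function(gsc, gm, da_dcc, vpd = NA_real_,
                      regime = NA_character_, cultivar = NA_character_) {
  for (nm in c("gsc", "gm", "da_dcc")) {
    v <- get(nm)
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop("partition requires strictly positive ", nm)
    }
  }
  gtot <- total_conductance(gsc, gm)
  k <- da_dcc
  denom <- gtot + k
  ls <- (gtot / gsc) * k / denom
  lm_ <- (gtot / gm) * k / denom
  lb <- gtot / denom
  structure(
    data.frame(vpd = vpd, regime = regime, cultivar = cultivar,
               ls = ls, lm = lm_, lb = lb, da_dcc = k,
               gsc = gsc, gm = gm, gtot = gtot,
               stringsAsFactors = FALSE),
    class = c("limitation_partition", "data.frame"))
}

#' Limitation partition profile across a VPD gradient
#'
#' Applies [partition()] per VPD level and fits ordinary least-squares
#' linear trends of each fraction on VPD per regime/cultivar group.
#'
#' @param profile Data.frame with one row per VPD level: columns `vpd`,
#'   `gsc`, `gm`, `da_dcc` and optional `regime`, `cultivar`.
#' @return List with `partitions` (a `"limitation_partition"` data.frame)
#'   and `trends` (per group and fraction: slope, intercept, r2, n).
#' @export
#' @examples
#' prof <- data.frame(vpd = c(0.5, 1.5, 2.5), gsc = c(0.5, 0.39, 0.27),
#'                    gm = c(0.59, 0.46, 0.34), da_dcc = c(0.14, 0.13, 0.12))
#' partition_profile(prof)$trends
partition_profile <- function(profile) {
  if (nrow(profile) < 3) stop("need >= 3 VPD levels")
  if (!"regime" %in% names(profile)) profile$regime <- "all"
  if (!"cultivar" %in% names(profile)) profile$cultivar <- "all"
  parts <- partition(profile$gsc, profile$gm, profile$da_dcc,
                     vpd = profile$vpd, regime = profile$regime,
                     cultivar = profile$cultivar)
  groups <- split(parts, interaction(parts$regime, parts$cultivar, drop = TRUE))
  trends <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(c("ls", "lm", "lb"), function(frac) {
      fit <- stats::lm(g[[frac]] ~ g$vpd)
      data.frame(regime = g$regime[1], cultivar = g$cultivar[1],
                 fraction = frac,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = suppressWarnings(summary(fit)$r.squared), n = nrow(g),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(trends) <- NULL
  list(partitions = parts, trends = trends)
}
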