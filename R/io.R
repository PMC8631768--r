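#' Read a gas-exchange CSV table
#'
#' Reads an instrument-style gas-exchange export (CSV, header, UTF-8, "."
#' decimal separator). Common instrument column aliases are accepted
#' case-insensitively (`Photo` for `pn`, `Cond` for `gsw`, `Ci` for
#' `ci_umol_mol`, `Tleaf` for `t_leaf_c`, `PARi` for `ppfd`, `CO2S` for
#' `ca_umol_mol`, `VpdL` for `vpd_kpa`, `PhiPS2` for `phi_psii`). Rows with
#' unparseable numeric fields are skipped with their line numbers reported;
#' a `gsw` above 10 mol m-2 s-1 triggers a suspected-mmol-units warning but
#' the row is kept.
#'
#' @param path Path to a CSV file.
#' @return Data.frame of validated records with canonical column names;
#'   attribute `skipped` holds the 1-based data-row numbers dropped.
#' @export
read_gas_exchange_table <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  aliases <- c(
    sample_id = "sample_id", regime = "regime", cultivar = "cultivar",
    vpd_kpa = "vpd_kpa", vpdl = "vpd_kpa",
    t_leaf_c = "t_leaf_c", tleaf = "t_leaf_c",
    ppfd = "ppfd", pari = "ppfd",
    ca_umol_mol = "ca_umol_mol", co2s = "ca_umol_mol",
    pn = "pn", photo = "pn",
    gsw = "gsw", cond = "gsw",
    ci_umol_mol = "ci_umol_mol", ci = "ci_umol_mol",
    phi_psii = "phi_psii", phips2 = "phi_psii",
    light_level = "light_level", o2_mmol_mol = "o2_mmol_mol"
  )
  lown <- tolower(names(raw))
  mapped <- aliases[lown]
  keep <- !is.na(mapped)
  raw <- raw[, keep, drop = FALSE]
  names(raw) <- mapped[keep]
  required <- c("vpd_kpa", "t_leaf_c", "ppfd", "ca_umol_mol", "pn", "gsw",
                "ci_umol_mol")
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         " (aliases accepted: Photo, Cond, Ci, Tleaf, PARi, CO2S, VpdL)")
  }
  numcols <- intersect(c(required, "phi_psii", "light_level", "o2_mmol_mol"),
                       names(raw))
  parsed <- raw
  for (cl in numcols) parsed[[cl]] <- suppressWarnings(as.numeric(raw[[cl]]))
  bad_row <- rowSums(is.na(parsed[, required, drop = FALSE]) &
                       !is.na(raw[, required, drop = FALSE]) |
                       is.na(raw[, required, drop = FALSE])) > 0
  if (any(bad_row)) {
    message(sum(bad_row), " unparseable row(s) skipped (data rows: ",
            paste(which(bad_row), collapse = ", "), ")")
  }
  out <- parsed[!bad_row, , drop = FALSE]
  if (any(out$gsw > 10)) {
    warning(sum(out$gsw > 10), " row(s) with gsw > 10 mol m-2 s-1: ",
            "suspected mmol units; rows kept unchanged")
  }
  if (any(out$ci_umol_mol >= 2000)) {
    warning("Ci >= 2000 umol mol-1 in ", sum(out$ci_umol_mol >= 2000),
            " row(s): check units")
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- which(bad_row)
  out
}

#' Write a table as TSV at fixed precision
#'
#' UTF-8, tab-separated, "." decimal separator; numeric columns rounded to
#' `digits` significant digits so that rewrites of identical inputs are
#' byte-identical.
#'
#' @param x Data.frame.
#' @param path Output path.
#' @param digits Significant digits (default 6).
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path, digits = 6) {
  y <- x
  for (cl in names(y)) {
    if (is.numeric(y[[cl]])) y[[cl]] <- signif(y[[cl]], digits)
  }
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
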