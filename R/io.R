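# Text formats: whitespace/comma-delimited reflectivity columns matching
# common beamline exports, CSV tension tables, YAML/JSON model configs.

#' Read a reflectivity curve from a text file
#'
#' Parses whitespace- or comma-delimited columns `qz, R[, dR]`; lines
#' starting with `#` are comments. `qz` is in Å⁻¹ unless `units = "nm^-1"`,
#' in which case values are converted (× 0.1).
#'
#' @param path File path.
#' @param units `"A^-1"` (default) or `"nm^-1"`.
#' @param normalized Logical flag stored on the returned curve.
#' @return A [reflectivity_curve()].
#' @export
read_reflectivity <- function(path, units = c("A^-1", "nm^-1"),
                              normalized = FALSE) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows)) stop("no data rows in ", path)
  parsed <- lapply(rows, function(i) {
    fields <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2 || any(is.na(vals)))
      stop("malformed row at line ", i, " of ", path, ": ", lines[i])
    vals
  })
  ncols <- unique(lengths(parsed))
  if (length(ncols) != 1)
    stop("inconsistent column counts in ", path)
  m <- do.call(rbind, parsed)
  qz <- m[, 1]
  if (units == "nm^-1") qz <- qz * 0.1
  if (any(diff(qz) <= 0)) {
    bad <- rows[which(diff(qz) <= 0)[1] + 1]
    stop("qz not strictly increasing at line ", bad, " of ", path)
  }
  if (any(m[, 2] < 0)) {
    bad <- rows[which(m[, 2] < 0)[1]]
    stop("negative reflectivity at line ", bad, " of ", path)
  }
  reflectivity_curve(qz, m[, 2], dr = if (ncols >= 3) m[, 3],
                     normalized = normalized)
}

#' Write a reflectivity curve as two/three-column text
#'
#' @param curve A [reflectivity_curve()].
#' @param path Output path.
#' @param comment Optional character vector written as leading `#` lines
#'   (e.g. seed and configuration hash).
#' @return `path`, invisibly.
#' @export
write_reflectivity <- function(curve, path, comment = NULL) {
  stopifnot(inherits(curve, "reflectivity_curve"))
  hdr <- c(
    if (!is.null(comment)) paste("#", comment),
    paste("# columns: qz[1/A] r", if (!is.null(curve$dr)) "dr" else ""),
    if (curve$normalized) "# normalized: R/RF"
  )
  m <- cbind(curve$qz, curve$r)
  if (!is.null(curve$dr)) m <- cbind(m, curve$dr)
  body <- apply(m, 1, function(row) paste(sprintf("%.15g", row),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Export an electron density profile as two-column text
#'
#' @param profile An `"edp"` from [build_edp()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edp <- function(profile, path) {
  stopifnot(inherits(profile, "edp"))
  writeLines(c("# columns: z[A] rho[e-/A^3]",
               sprintf("%.15g %.15g", profile$z, profile$rho)), path)
  invisible(path)
}

#' Read a tension isotherm from CSV
#'
#' Columns: concentration (mM), gamma (mN/m), optionally sd (mN/m);
#' `#` comment lines are skipped.
#'
#' @param path File path.
#' @param gamma0 Clean-interface tension in mN/m.
#' @param temperature Temperature in K.
#' @return A [tension_isotherm()].
#' @export
read_tension <- function(path, gamma0 = 72.5, temperature = 296.15) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  if (ncol(df) < 2) stop("need at least concentration and gamma columns")
  tension_isotherm(df[[1]], df[[2]], sd = if (ncol(df) >= 3) df[[3]],
                   gamma0 = gamma0, temperature = temperature)
}

#' Write a tension isotherm as CSV
#'
#' @param iso A [tension_isotherm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tension <- function(iso, path) {
  stopifnot(inherits(iso, "tension_isotherm"))
  df <- data.frame(concentration_mM = iso$concentration,
                   gamma_mN_m = iso$gamma, sd_mN_m = iso$sd)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an interface model from a YAML or JSON config
#'
#' Expected structure:
#' ```yaml
#' rho_air: 0
#' rho_subphase: 0.334
#' shared_sigma: 3.594   # optional
#' slabs:
#'   - {d: 10.63, rho: 0.312, sigma: 3.594}
#'   - {d: 5.025, rho: 0.350, sigma: 3.594}
#' ```
#'
#' @param path `.yml`/`.yaml` or `.json` file.
#' @return An [interface_model()].
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  slabs <- lapply(cfg$slabs %||% list(), function(s)
    slab(s$d, s$rho, s$sigma %||% 0))
  interface_model(slabs,
                  rho_air = cfg$rho_air %||% 0,
                  rho_subphase = cfg$rho_subphase %||% xrr_constants$rho_water,
                  shared_sigma = cfg$shared_sigma,
                  sigma_air = cfg$sigma_air)
}

#' Write a composition report as CSV
#'
#' One row per species with surface excesses, plus the reference species'
#' area per molecule and hydration number, mirroring the layout of the
#' standard surface-concentration summary tables.
#'
#' @param composition A `"monolayer_composition"` from
#'   [mixed_layer_composition()].
#' @param path Output path.
#' @param comment Optional character vector of `#` header lines.
#' @return `path`, invisibly.
#' @export
write_composition <- function(composition, path, comment = NULL) {
  stopifnot(inherits(composition, "monolayer_composition"))
  df <- data.frame(species = names(composition$gamma),
                   gamma_mg_m2 = as.numeric(composition$gamma),
                   n_per_A2 = as.numeric(composition$n))
  df$A_s_A2 <- ifelse(df$species == composition$reference,
                      composition$A_s, NA)
  df$N_W <- ifelse(df$species == composition$reference,
                   composition$N_W, NA)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
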