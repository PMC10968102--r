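# Delimited-text interfaces. Tables use the field's conventional units
# (mM, Celsius); everything is converted to molar / Kelvin on read.

#' Read a titration table (CSV)
#'
#' Expected columns: `peptide_id`, `p0_mM`, `det0_mM`, `temperature_C`,
#' `f_dimer`, optional `f_dimer_err`.
#'
#' @param path CSV file path.
#' @return data frame with molar `p0`, `det0` and Kelvin `temperature`.
#' @export
read_titration_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("p0_mM", "det0_mM", "temperature_C", "f_dimer")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("titration CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$p0 <- df$p0_mM * 1e-3
  df$det0 <- df$det0_mM * 1e-3
  df$temperature <- celsius_to_kelvin(df$temperature_C)
  df
}

#' Write a titration table (CSV)
#'
#' Inverse of [read_titration_csv()].
#'
#' @param points data frame with molar `p0`, `det0`, Kelvin `temperature`,
#'   `f_dimer` and optionally `f_dimer_err`, `peptide_id`.
#' @param path output CSV path.
#' @param peptide_id used when `points` lacks a `peptide_id` column.
#' @return the path, invisibly.
#' @export
write_titration_csv <- function(points, path, peptide_id = "peptide") {
  out <- data.frame(
    peptide_id = if ("peptide_id" %in% names(points)) points$peptide_id
                 else peptide_id,
    p0_mM = points$p0 * 1e3,
    det0_mM = points$det0 * 1e3,
    temperature_C = points$temperature - .CELSIUS_OFFSET,
    f_dimer = points$f_dimer)
  if ("f_dimer_err" %in% names(points)) out$f_dimer_err <- points$f_dimer_err
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a free-energy temperature series (CSV)
#'
#' Expected columns: `temperature_C`, `delta_g_kcal_mol`, optional `se`.
#'
#' @param path CSV file path.
#' @return data frame with Kelvin `temperature` and `delta_g` (kcal/mol).
#' @export
read_delta_g_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("temperature_C", "delta_g_kcal_mol")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("free-energy CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$temperature <- celsius_to_kelvin(df$temperature_C)
  df$delta_g <- df$delta_g_kcal_mol
  df
}

#' Write a spectrum to a two-column CSV (ppm, intensity)
#'
#' A JSON sidecar `<stem>.meta.json` records the sample metadata needed to
#' re-analyse the trace.
#'
#' @param spectrum a [spectrum1d].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  write.csv(data.frame(ppm = spectrum$ppm, intensity = spectrum$intensity),
            path, row.names = FALSE)
  meta <- list(id = spectrum$id, sfrq = spectrum$sfrq,
               temperature = spectrum$temperature,
               p0 = spectrum$p0, det0 = spectrum$det0)
  jsonlite::write_json(meta, sub("\\.csv$", ".meta.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spectrum written by [write_spectrum_csv()]
#'
#' @param path CSV path (a matching `.meta.json` sidecar must exist).
#' @return a [spectrum1d].
#' @export
read_spectrum_csv <- function(path) {
  df <- read.csv(path)
  meta_path <- sub("\\.csv$", ".meta.json", path)
  if (!file.exists(meta_path))
    stop("missing sidecar metadata: ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  spectrum1d(df$ppm, df$intensity, sfrq = meta$sfrq,
             temperature = meta$temperature %||% NA_real_,
             p0 = meta$p0 %||% NA_real_, det0 = meta$det0 %||% NA_real_,
             id = meta$id %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
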