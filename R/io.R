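#' Read and write spectra as CSV
#'
#' Plain two-column CSV dialect: `wavelength_nm` plus a value column
#' named after the kind (`transmittance` for transmittance spectra,
#' `value` otherwise).
#'
#' @param path file path.
#' @param kind spectrum kind (see [spectrum()]).
#' @return `read_spectrum_csv()`: an `hb_spectrum`;
#'   `write_spectrum_csv()`: `path`, invisibly.
#' @export
read_spectrum_csv <- function(path, kind) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"wavelength_nm" %in% names(df)) {
    stop("CSV must contain a `wavelength_nm` column", call. = FALSE)
  }
  vcol <- setdiff(names(df), "wavelength_nm")[1]
  spectrum(df$wavelength_nm, df[[vcol]], kind)
}

#' @rdname read_spectrum_csv
#' @param x an `hb_spectrum`.
#' @export
write_spectrum_csv <- function(x, path) {
  stopifnot(inherits(x, "hb_spectrum"))
  kind <- spectrum_kind(x)
  vname <- if (kind == "transmittance") "transmittance" else "value"
  df <- stats::setNames(
    tibble::tibble(x$wavelength_nm, x$value), c("wavelength_nm", vname))
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a transmittance measurement (CSV + JSON sidecar)
#'
#' The spectrum CSV has columns `wavelength_nm`, `transmittance`; the
#' sidecar JSON carries `path_length_mm`, `volume_fraction`, `ppv` and
#' optionally `stock_concentration_per_pL`.
#'
#' @param csv_path spectrum CSV path.
#' @param meta_path sidecar JSON path; defaults to the CSV path with a
#'   `.json` extension.
#' @return a [transmittance_measurement()].
#' @export
read_transmittance_measurement <- function(csv_path, meta_path = NULL) {
  if (is.null(meta_path)) {
    meta_path <- sub("\\.csv$", ".json", csv_path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  transmittance_measurement(
    read_spectrum_csv(csv_path, "transmittance"),
    path_length_mm = meta$path_length_mm,
    volume_fraction = meta$volume_fraction,
    ppv = meta$ppv,
    stock_concentration = meta$stock_concentration_per_pL)
}

#' @rdname read_transmittance_measurement
#' @param m a [transmittance_measurement()].
#' @param csv_path output CSV path (sidecar JSON written next to it).
#' @export
write_transmittance_measurement <- function(m, csv_path) {
  stopifnot(inherits(m, "transmittance_measurement"))
  write_spectrum_csv(m$spectrum, csv_path)
  meta <- list(path_length_mm = m$path_length_mm,
               volume_fraction = m$volume_fraction)
  if (!is.null(m$ppv)) meta$ppv <- m$ppv
  if (!is.null(m$stock_concentration)) {
    meta$stock_concentration_per_pL <- m$stock_concentration
  }
  jsonlite::write_json(meta, sub("\\.csv$", ".json", csv_path),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Read and write species optics tables
#'
#' CSV dialect with header columns `wavelength_nm`, `alpha_ml_per_g`,
#' `gamma_ml_per_g`, so users can substitute authoritative literature
#' increment tables for the bundled synthetic ones.
#'
#' @param path CSV path.
#' @param species species name (see [species_optics()]).
#' @param molar_mass molar mass (g/mol).
#' @return `read_species_optics()`: a [species_optics()];
#'   `write_species_optics()`: `path`, invisibly.
#' @export
read_species_optics <- function(path, species,
                                molar_mass = hb_monomer_mass()) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("wavelength_nm", "alpha_ml_per_g", "gamma_ml_per_g")
  if (!all(need %in% names(df))) {
    stop("species optics CSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  species_optics(
    species,
    alpha = spectrum(df$wavelength_nm, df$alpha_ml_per_g,
                     "ri_increment_real"),
    gamma = spectrum(df$wavelength_nm, df$gamma_ml_per_g,
                     "ri_increment_imag"),
    molar_mass = molar_mass)
}

#' @rdname read_species_optics
#' @param x a [species_optics()].
#' @export
write_species_optics <- function(x, path) {
  stopifnot(inherits(x, "species_optics"))
  readr::write_csv(tibble::tibble(
    wavelength_nm = x$alpha$wavelength_nm,
    alpha_ml_per_g = x$alpha$value,
    gamma_ml_per_g = x$gamma$value), path)
  invisible(path)
}

#' Read and write a density panel as JSON
#'
#' @param path JSON path.
#' @return `read_density_panel()`: a [density_panel()].
#' @export
read_density_panel <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  density_panel(rho_sus = p$rho_sus, rho_sup = p$rho_sup,
                rho_rac = p$rho_rac, ppv = p$ppv,
                di_hb = p$di_hb, di_glhsa = p$di_glhsa)
}

#' @rdname read_density_panel
#' @param panel a [density_panel()].
#' @export
write_density_panel <- function(panel, path) {
  stopifnot(inherits(panel, "density_panel"))
  jsonlite::write_json(unclass(panel), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
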