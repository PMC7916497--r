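#' Spectra as tibbles
#'
#' A spectrum is a tibble with columns `wavelength_nm` (vacuum wavelength,
#' strictly increasing) and `value`, carrying a `kind` attribute that states
#' what the values are.  All pipeline functions accept and return these
#' tibbles, so spectra chain naturally with dplyr verbs and the pipe.
#'
#' Recognised kinds: `"transmittance"`, `"extinction_cross_section"` (um^2),
#' `"vsecs"` (um^-1), `"molar_extinction"` (L mol^-1 cm^-1),
#' `"ri_increment_real"` (mL/g), `"ri_increment_imag"` (mL/g),
#' `"absorbance"`, `"refractive_index"` (absolute, e.g. the host medium).
#'
#' @param wavelength_nm numeric vector of vacuum wavelengths in nm,
#'   strictly increasing.
#' @param value numeric vector, same length as `wavelength_nm`.
#' @param kind character scalar, one of the kinds listed above.
#' @return A tibble of class `hb_spectrum` with columns `wavelength_nm`
#'   and `value` and attribute `kind`.
#' @examples
#' s <- spectrum(seq(300, 800, 10), rep(0.5, 51), "transmittance")
#' spectrum_kind(s)
#' @export
spectrum <- function(wavelength_nm, value, kind) {
  kind <- match.arg(kind, spectrum_kinds())
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) != length(value)) {
    stop("`wavelength_nm` and `value` must have the same length", call. = FALSE)
  }
  if (length(wavelength_nm) == 0L) {
    stop("a spectrum needs at least one wavelength", call. = FALSE)
  }
  if (anyNA(wavelength_nm) || any(diff(wavelength_nm) <= 0)) {
    stop("`wavelength_nm` must be strictly increasing and free of NA",
         call. = FALSE)
  }
  x <- tibble::tibble(wavelength_nm = wavelength_nm, value = value)
  x <- tibble::new_tibble(x, kind = kind, class = "hb_spectrum")
  validate_spectrum(x)
  x
}

spectrum_kinds <- function() {
  c("transmittance", "extinction_cross_section", "vsecs",
    "molar_extinction", "ri_increment_real", "ri_increment_imag",
    "absorbance", "refractive_index")
}

#' @rdname spectrum
#' @param x an `hb_spectrum`.
#' @export
spectrum_kind <- function(x) attr(x, "kind", exact = TRUE)

#' Validate spectrum invariants
#'
#' Checks the kind-specific value constraints: transmittance in (0, 1],
#' molar extinction and imaginary increments non-negative.
#'
#' @param x an `hb_spectrum`.
#' @return `x`, invisibly, or an error.
#' @export
validate_spectrum <- function(x) {
  stopifnot(inherits(x, "hb_spectrum"))
  kind <- spectrum_kind(x)
  v <- x$value
  if (anyNA(v)) stop("spectrum values must not contain NA", call. = FALSE)
  switch(kind,
    transmittance = {
      if (any(v <= 0 | v > 1)) {
        stop("transmittance values must lie in (0, 1]", call. = FALSE)
      }
    },
    molar_extinction = ,
    ri_increment_imag = {
      if (any(v < 0)) {
        stop(sprintf("%s values must be >= 0", kind), call. = FALSE)
      }
    },
    NULL
  )
  invisible(x)
}

new_spectrum_like <- function(template, value, kind) {
  spectrum(template$wavelength_nm, value, kind)
}

#' Interpolate a spectrum onto a new wavelength grid
#'
#' Linear interpolation; requested wavelengths must lie inside the
#' spectrum's range (no extrapolation).
#'
#' @param x an `hb_spectrum`.
#' @param wavelength_nm target grid (nm).
#' @return an `hb_spectrum` on the new grid with the same kind.
#' @export
spectrum_interp <- function(x, wavelength_nm) {
  stopifnot(inherits(x, "hb_spectrum"))
  rng <- range(x$wavelength_nm)
  if (any(wavelength_nm < rng[1] - 1e-9 | wavelength_nm > rng[2] + 1e-9)) {
    stop("requested wavelengths outside the tabulated range (",
         rng[1], "-", rng[2], " nm)", call. = FALSE)
  }
  v <- stats::approx(x$wavelength_nm, x$value, xout = wavelength_nm,
                     rule = 1)$y
  spectrum(wavelength_nm, v, spectrum_kind(x))
}

#' Restrict a spectrum to a wavelength window
#'
#' @param x an `hb_spectrum`.
#' @param lower,upper window bounds in nm (inclusive).
#' @return an `hb_spectrum` containing the grid points inside the window.
#' @export
spectrum_window <- function(x, lower = 300, upper = 800) {
  stopifnot(inherits(x, "hb_spectrum"))
  keep <- x$wavelength_nm >= lower & x$wavelength_nm <= upper
  if (!any(keep)) stop("no grid points inside the requested window",
                       call. = FALSE)
  spectrum(x$wavelength_nm[keep], x$value[keep], spectrum_kind(x))
}

same_grid <- function(a, b, tol = 1e-9) {
  length(a$wavelength_nm) == length(b$wavelength_nm) &&
    all(abs(a$wavelength_nm - b$wavelength_nm) <= tol)
}

require_same_grid <- function(...) {
  xs <- list(...)
  ref <- xs[[1]]
  for (x in xs[-1]) {
    if (!same_grid(ref, x)) {
      stop("spectra must share a common wavelength grid", call. = FALSE)
    }
  }
  invisible(ref$wavelength_nm)
}
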