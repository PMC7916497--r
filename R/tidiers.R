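#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a hemoglobin composition fit
#'
#' One row per fitted fraction; the metHb row carries the profile-based
#' standard uncertainty.
#'
#' @param x an `hb_fit`.
#' @param ... unused.
#' @return tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.hb_fit <- function(x, ...) {
  f <- x$fractions
  tibble::tibble(
    term = c("phi_oxy", "phi_deoxy", "phi_met"),
    estimate = c(f$phi_oxy, f$phi_deoxy, f$phi_met),
    std.error = c(NA_real_, NA_real_, x$uncertainty_met))
}

#' Glance at a hemoglobin composition fit
#'
#' @param x an `hb_fit`.
#' @param ... unused.
#' @return one-row tibble with fit-level summaries.
#' @export
glance.hb_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, scale = x$scale,
                 u_phi_met = x$uncertainty_met,
                 nobs = x$n_wavelengths, mode = x$mode,
                 allow_scale = x$allow_scale,
                 ill_posed = x$ill_posed)
}
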