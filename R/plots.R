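#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrum
#'
#' Line plot of the spectrum against wavelength, labelled by kind.
#'
#' @param object an `hb_spectrum`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.hb_spectrum <- function(object, ...) {
  kind <- spectrum_kind(object)
  ylab <- switch(kind,
                 transmittance = "transmittance",
                 extinction_cross_section =
                   expression(bar(C)[ext] ~ (mu * m^2)),
                 vsecs = expression(Z ~ (mu * m^{-1})),
                 molar_extinction =
                   expression(epsilon ~ (L ~ mol^{-1} ~ cm^{-1})),
                 ri_increment_real = expression(alpha ~ (mL / g)),
                 ri_increment_imag = expression(gamma ~ (mL / g)),
                 kind)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$wavelength_nm, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot a composition fit
#'
#' Measured versus fitted volume-specific extinction spectra.
#'
#' @param object an `hb_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.hb_fit <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(wavelength_nm = object$z_meas$wavelength_nm,
                   value = object$z_meas$value, which = "measured"),
    tibble::tibble(wavelength_nm = object$fitted$wavelength_nm,
                   value = object$fitted$value, which = "fitted"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength_nm,
                                   y = .data$value,
                                   linetype = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)",
                  y = expression(Z ~ (mu * m^{-1})),
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' QC plot of a dilution series
#'
#' Volume-specific extinction spectra of every series member on a log
#' scale; consistent members differ only by a vertical shift.
#'
#' @param series list of [transmittance_measurement()]s.
#' @return a ggplot.
#' @export
plot_dilution_qc <- function(series) {
  df <- purrr::map_dfr(series, function(m) {
    z <- transmittance_to_vsecs(m)
    tibble::tibble(wavelength_nm = z$wavelength_nm, z = z$value,
                   phi = format(m$volume_fraction, digits = 3))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength_nm, y = .data$z,
                                   colour = .data$phi)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "wavelength (nm)",
                  y = expression(Z ~ (mu * m^{-1})),
                  colour = expression(varphi)) +
    ggplot2::theme_minimal()
}
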