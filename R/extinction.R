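#' A collimated transmittance measurement
#'
#' Couples a transmittance spectrum with the geometry and dilution
#' metadata needed to convert it to extinction quantities: the cuvette
#' absorption length, the volume fraction of stock suspension in the
#' cuvette, the packed particle volume (PPV) of the stock and optionally
#' the stock particle concentration.
#'
#' @param spectrum `hb_spectrum` of kind `transmittance`.
#' @param path_length_mm cuvette absorption length (mm), > 0.
#' @param volume_fraction volume fraction of stock in the measurement
#'   suspension, in (0, 1).
#' @param ppv packed particle volume of the stock, in (0, 1); required
#'   for the volume-specific route.
#' @param stock_concentration particle concentration of the stock in
#'   pL^-1; required for the per-particle route.
#' @return list of class `transmittance_measurement`.
#' @export
transmittance_measurement <- function(spectrum, path_length_mm = 10,
                                      volume_fraction, ppv = NULL,
                                      stock_concentration = NULL) {
  stopifnot(inherits(spectrum, "hb_spectrum"))
  if (spectrum_kind(spectrum) != "transmittance") {
    stop("`spectrum` must be of kind transmittance", call. = FALSE)
  }
  if (!is.numeric(path_length_mm) || path_length_mm <= 0) {
    stop("`path_length_mm` must be > 0", call. = FALSE)
  }
  if (!is.numeric(volume_fraction) || volume_fraction <= 0 ||
      volume_fraction >= 1) {
    stop("`volume_fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(ppv) && (ppv <= 0 || ppv >= 1)) {
    stop("`ppv` must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(stock_concentration) && stock_concentration <= 0) {
    stop("`stock_concentration` must be > 0 (pL^-1)", call. = FALSE)
  }
  structure(list(spectrum = spectrum, path_length_mm = path_length_mm,
                 volume_fraction = volume_fraction, ppv = ppv,
                 stock_concentration = stock_concentration),
            class = "transmittance_measurement")
}

#' Average extinction cross section from transmittance
#'
#' Beer-Lambert inversion per particle:
#' \deqn{\bar C_{ext}(\lambda) = -\frac{\ln T(\lambda)}{\ell\, C_0\,
#'   \varphi},}
#' with the path length \eqn{\ell} converted to um and the stock
#' concentration \eqn{C_0} from pL^-1 to um^-3 (1 pL = 10^3 um^3).
#'
#' @param m a [transmittance_measurement()] with `stock_concentration`
#'   set.
#' @return `hb_spectrum` of kind `extinction_cross_section` (um^2).
#' @export
transmittance_to_cext <- function(m) {
  stopifnot(inherits(m, "transmittance_measurement"))
  if (is.null(m$stock_concentration)) {
    stop("`stock_concentration` is required for the per-particle route",
         call. = FALSE)
  }
  tvals <- m$spectrum$value
  if (any(tvals <= 0)) {
    stop("transmittance saturated at zero: cannot invert", call. = FALSE)
  }
  ell_um <- m$path_length_mm * 1000
  c0_um3 <- m$stock_concentration * 1e-3  # pL^-1 -> um^-3
  cext <- -log(tvals) / (ell_um * c0_um3 * m$volume_fraction)
  new_spectrum_like(m$spectrum, cext, "extinction_cross_section")
}

#' Volume-specific extinction cross section from transmittance
#'
#' Concentration-free inversion
#' \deqn{Z(\lambda) = -\frac{\ln T(\lambda)}{\ell\, \mathrm{PPV}\,
#'   \varphi}}
#' in um^-1, which replaces the poorly known particle concentration by
#' the packed particle volume of the stock.
#'
#' @param m a [transmittance_measurement()] with `ppv` set.
#' @return `hb_spectrum` of kind `vsecs` (um^-1).
#' @export
transmittance_to_vsecs <- function(m) {
  stopifnot(inherits(m, "transmittance_measurement"))
  if (is.null(m$ppv)) {
    stop("`ppv` is required for the volume-specific route", call. = FALSE)
  }
  tvals <- m$spectrum$value
  if (any(tvals <= 0)) {
    stop("transmittance saturated at zero: cannot invert", call. = FALSE)
  }
  ell_um <- m$path_length_mm * 1000
  z <- -log(tvals) / (ell_um * m$ppv * m$volume_fraction)
  new_spectrum_like(m$spectrum, z, "vsecs")
}

#' Select the working dilution from a dilution series
#'
#' Picks the densest member of a transmittance dilution series that is
#' free of multiple-scattering artefacts: its transmittance must stay at
#' or above `t_min` everywhere in the QC window, and its log-Z curve,
#' after removing the best constant shift (pipetting volume errors move
#' curves up or down on a log scale without changing their shape), must
#' agree with the next more dilute member to within `rms_tol` RMS.
#'
#' @param series list of [transmittance_measurement()]s (any order).
#' @param t_min minimum acceptable transmittance in the window
#'   (default 0.30).
#' @param rms_tol maximum RMS deviation of the shifted log-Z curves
#'   (default 0.02, i.e. 2%).
#' @param window QC wavelength window in nm, default `c(300, 800)`.
#' @return the selected [transmittance_measurement()], with the per-member
#'   diagnostics tibble attached as attribute `"qc"`.
#' @export
select_dilution <- function(series, t_min = 0.30, rms_tol = 0.02,
                            window = c(300, 800)) {
  if (length(series) == 0L) stop("`series` is empty", call. = FALSE)
  stopifnot(all(vapply(series, inherits, logical(1),
                       "transmittance_measurement")))
  phi <- vapply(series, function(m) m$volume_fraction, numeric(1))
  ord <- order(phi, decreasing = TRUE)
  series <- series[ord]
  phi <- phi[ord]
  zlist <- lapply(series, function(m) {
    spectrum_window(transmittance_to_vsecs(m), window[1], window[2])
  })
  tmin_obs <- vapply(series, function(m) {
    min(spectrum_window(m$spectrum, window[1], window[2])$value)
  }, numeric(1))
  n <- length(series)
  shift_rms <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i < n) {
      d <- log(pmax(zlist[[i]]$value, 1e-300)) -
        log(pmax(zlist[[i + 1]]$value, 1e-300))
      shift_rms[i] <- sqrt(mean((d - mean(d))^2))
    }
  }
  pass_t <- tmin_obs >= t_min - 1e-12
  pass_shift <- is.na(shift_rms) | shift_rms <= rms_tol
  qc <- tibble::tibble(volume_fraction = phi, t_min_window = tmin_obs,
                       log_shift_rms = shift_rms,
                       pass_transmittance = pass_t,
                       pass_shift = pass_shift,
                       pass = pass_t & pass_shift)
  sel <- which(qc$pass)[1]
  if (is.na(sel)) {
    stop("no dilution passes QC (min T >= ", t_min, " and log-shift RMS <= ",
         rms_tol, "); inspect the diagnostics: ",
         paste(utils::capture.output(print(qc)), collapse = "\n"),
         call. = FALSE)
  }
  out <- series[[sel]]
  attr(out, "qc") <- qc
  out
}

#' Least-squares rescaling of a VSECS spectrum onto a reference
#'
#' Fits a single multiplicative factor
#' \eqn{s = \arg\min_s \sum_\lambda (s z - z_{ref})^2 =
#'   \sum z z_{ref} / \sum z^2}
#' over the common wavelength range, as used to correct for particle
#' loss (e.g. foaming during gas bubbling reduces the effective PPV and
#' scales Z down uniformly).
#'
#' @param z,z_ref `hb_spectrum`s of kind `vsecs` on a common grid
#'   covering the fit window.
#' @param window wavelength window (nm) for the least squares, default
#'   `c(300, 800)`.
#' @return list with elements `spectrum` (the rescaled `z`) and `scale`.
#' @export
rescale_to_reference <- function(z, z_ref, window = c(300, 800)) {
  stopifnot(inherits(z, "hb_spectrum"), inherits(z_ref, "hb_spectrum"))
  if (!same_grid(z, z_ref)) {
    stop("`z` and `z_ref` must share a common grid", call. = FALSE)
  }
  zw <- spectrum_window(z, window[1], window[2])
  rw <- spectrum_window(z_ref, window[1], window[2])
  if (all(zw$value == 0)) {
    stop("`z` is identically zero over the fit window", call. = FALSE)
  }
  s <- sum(zw$value * rw$value) / sum(zw$value^2)
  list(spectrum = new_spectrum_like(z, s * z$value, "vsecs"), scale = s)
}
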