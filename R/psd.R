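#' Log-normal particle size distribution
#'
#' Diameter distribution
#' \deqn{p(D) = \frac{1}{\sqrt{2\pi}\,\sigma_D}\,\frac{1}{D}\,
#'   \exp\!\left[-\frac{\ln^2(D/\mu_D)}{2\sigma_D^2}\right],}
#' parameterized by the median diameter \eqn{\mu_D} (nm) and the
#' dimensionless log-scale width \eqn{\sigma_D}.
#'
#' @param mu_d median diameter (nm), > 0.
#' @param sigma_d log-scale width, >= 0.
#' @return list of class `hb_psd`.
#' @export
lognormal_psd <- function(mu_d, sigma_d) {
  if (!is.numeric(mu_d) || mu_d <= 0 || !is.finite(mu_d)) {
    stop("`mu_d` must be a positive diameter in nm", call. = FALSE)
  }
  if (!is.numeric(sigma_d) || sigma_d < 0 || !is.finite(sigma_d)) {
    stop("`sigma_d` must be >= 0", call. = FALSE)
  }
  structure(list(mu_d = mu_d, sigma_d = sigma_d), class = "hb_psd")
}

#' @export
print.hb_psd <- function(x, ...) {
  cat(sprintf("log-normal PSD: median %.4g nm, sigma_d %.4g (%.1f%%)\n",
              x$mu_d, x$sigma_d, 100 * x$sigma_d))
  invisible(x)
}

#' Quantile and density of a log-normal PSD
#'
#' `psd_quantile()` is \eqn{Q(p) = \mu_D \exp(\sigma_D z_p)} with
#' \eqn{z_p} the standard normal quantile; `psd_density()` evaluates
#' p(D).
#'
#' @param psd an `hb_psd`.
#' @param p probabilities in (0, 1).
#' @param diameter_nm diameters (nm).
#' @return numeric vector.
#' @export
psd_quantile <- function(psd, p) {
  stopifnot(inherits(psd, "hb_psd"))
  psd$mu_d * exp(psd$sigma_d * stats::qnorm(p))
}

#' @rdname psd_quantile
#' @export
psd_density <- function(psd, diameter_nm) {
  stopifnot(inherits(psd, "hb_psd"))
  if (psd$sigma_d == 0) {
    stop("density undefined for a monodisperse (sigma_d = 0) PSD",
         call. = FALSE)
  }
  stats::dlnorm(diameter_nm, meanlog = log(psd$mu_d), sdlog = psd$sigma_d)
}

#' Convert a measured (median, width) summary to PSD parameters
#'
#' Sizing instruments report the median diameter and the 16%-84%
#' inter-quantile width \eqn{w = Q(84\%) - Q(16\%)}.  With the exact
#' normal quantile \eqn{z_{84} = z(0.84) \approx 0.994458} (not z = 1),
#' \eqn{w = 2\mu_D \sinh(\sigma_D z_{84})}, giving the closed form
#' \deqn{\sigma_D = \mathrm{asinh}\!\left(\frac{w}{2\mu_D}\right)/z_{84}.}
#' The exact-quantile convention is the one that reproduces the reference
#' batch widths (median 760 nm, w 395 nm -> sigma_d 25.8%; median 996 nm,
#' w 300 nm -> sigma_d 15.1%).
#'
#' @param median median diameter (nm), > 0.
#' @param width_16_84 inter-quantile width (nm), >= 0.
#' @return an `hb_psd`.
#' @examples
#' lognormal_from_summary(760, 395)  # sigma_d ~ 0.258
#' @export
lognormal_from_summary <- function(median, width_16_84) {
  if (!is.numeric(median) || median <= 0) {
    stop("`median` must be > 0", call. = FALSE)
  }
  if (!is.numeric(width_16_84) || width_16_84 < 0 ||
      !is.finite(width_16_84)) {
    stop("`width_16_84` must be finite and >= 0", call. = FALSE)
  }
  z84 <- stats::qnorm(0.84)
  sigma <- asinh(width_16_84 / (2 * median)) / z84
  if (!is.finite(sigma)) {
    stop("width too large: sigma_d is not finite", call. = FALSE)
  }
  lognormal_psd(median, sigma)
}

#' Summarise a PSD as (median, width)
#'
#' Inverse of [lognormal_from_summary()].
#'
#' @param psd an `hb_psd`.
#' @return one-row tibble with `median`, `width_16_84`, `rel_width`.
#' @export
psd_summary <- function(psd) {
  stopifnot(inherits(psd, "hb_psd"))
  z84 <- stats::qnorm(0.84)
  w <- 2 * psd$mu_d * sinh(psd$sigma_d * z84)
  tibble::tibble(median = psd$mu_d, width_16_84 = w,
                 rel_width = w / psd$mu_d)
}

#' Mean particle volume of a PSD
#'
#' \eqn{\bar V = \int \frac{\pi}{6} D^3 p(D)\, dD}.  The closed form for
#' a log-normal PSD is \eqn{(\pi/6)\mu_D^3 \exp(4.5\sigma_D^2)}; the
#' quadrature route substitutes \eqn{D = \mu_D e^{\sigma_D z}} and
#' integrates the Gaussian-weighted integrand on a wide equidistant
#' z-grid (the volume-weighted tail extends three sigma beyond the
#' number-weighted one, so integrating in the log domain avoids the
#' truncation a diameter grid would suffer).  The two routes agree to
#' better than 1e-6 relative.
#'
#' @param psd an `hb_psd`.
#' @param method `"closed_form"` (default) or `"quadrature"`.
#' @param n_nodes number of quadrature nodes (quadrature route).
#' @return mean volume in um^3.
#' @export
mean_volume <- function(psd, method = c("closed_form", "quadrature"),
                        n_nodes = 2001) {
  stopifnot(inherits(psd, "hb_psd"))
  method <- match.arg(method)
  if (method == "closed_form" || psd$sigma_d == 0) {
    return(pi / 6 * (psd$mu_d * 1e-3)^3 * exp(4.5 * psd$sigma_d^2))
  }
  z <- seq(-10, 10, length.out = n_nodes)
  d_um <- psd$mu_d * 1e-3 * exp(psd$sigma_d * z)
  trapz(z, pi / 6 * d_um^3 * stats::dnorm(z))
}

# equidistant diameter grid spanning Q(0.1%)..Q(99.9%), step <= d_step,
# at least 51 nodes so narrow distributions stay resolved
psd_diameter_grid <- function(psd, d_step = 10) {
  if (d_step > 20) {
    stop("diameter quadrature step must be <= 20 nm", call. = FALSE)
  }
  lo <- psd_quantile(psd, 0.001)
  hi <- psd_quantile(psd, 0.999)
  n <- max(ceiling((hi - lo) / d_step) + 1L, 51L)
  seq(lo, hi, length.out = n)
}

#' Ensemble-averaged volume-specific extinction cross section
#'
#' Averages the single-sphere Lorenz-Mie extinction cross section over
#' the particle size distribution and divides by the mean particle
#' volume:
#' \deqn{\bar C_{ext}(\lambda) = \int C_{ext}(\lambda; D)\, p(D)\, dD,
#'   \qquad Z(\lambda) = \bar C_{ext}(\lambda)/\bar V.}
#' Both integrals use the same trapezoidal nodes (equidistant grid from
#' the 0.1% to the 99.9% diameter quantile, step at most 20 nm), so Z is
#' insensitive to the truncated distribution tails.  A monodisperse PSD
#' (`sigma_d = 0`) reduces to the single-sphere ratio at the median.
#'
#' @param psd an `hb_psd`.
#' @param ri `hb_complex_ri` table of the particle.
#' @param n_medium host RI spectrum on the same grid, or `NULL` for pure
#'   water.
#' @param d_step diameter quadrature step in nm (<= 20; default 10).
#' @return `hb_spectrum` of kind `vsecs` (um^-1).
#' @export
ensemble_vsecs <- function(psd, ri, n_medium = NULL, d_step = 10) {
  stopifnot(inherits(psd, "hb_psd"), inherits(ri, "hb_complex_ri"))
  lam <- ri$wavelength_nm
  if (is.null(n_medium)) n_medium <- water_ri(lam)
  stopifnot(inherits(n_medium, "hb_spectrum"))
  if (length(n_medium$wavelength_nm) != length(lam) ||
      any(abs(n_medium$wavelength_nm - lam) > 1e-9)) {
    stop("`n_medium` grid must match the RI grid", call. = FALSE)
  }
  m <- complex(real = ri$n, imaginary = ri$kappa)
  if (psd$sigma_d == 0) {
    cext <- mie_extinction(psd$mu_d, lam, m, n_medium$value)
    v <- pi / 6 * (psd$mu_d * 1e-3)^3
    return(spectrum(lam, cext / v, "vsecs"))
  }
  dg <- psd_diameter_grid(psd, d_step)
  nd <- length(dg)
  nl <- length(lam)
  # flatten (diameter, wavelength): diameter varies fastest
  cext <- mie_extinction(rep(dg, times = nl),
                         rep(lam, each = nd),
                         rep(m, each = nd),
                         rep(n_medium$value, each = nd))
  cmat <- matrix(cext, nrow = nd, ncol = nl)
  p <- psd_density(psd, dg)
  w <- trapz_weights(dg) * p
  cbar <- as.numeric(crossprod(cmat, w))
  vbar <- sum(w * pi / 6 * (dg * 1e-3)^3)
  spectrum(lam, cbar / vbar, "vsecs")
}

trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-1] + dx[-(n - 1)]) / 2
  w
}
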