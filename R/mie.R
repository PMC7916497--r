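#' Lorenz-Mie extinction cross section of a homogeneous sphere
#'
#' Exact series solution for scattering and absorption by a homogeneous
#' sphere in a non-absorbing host medium.  The size parameter is
#' \eqn{x = \pi D n_{med}/\lambda} (vacuum wavelength), the relative index
#' \eqn{m = m_{particle}/n_{med}}, and
#' \deqn{C_{ext} = \frac{2\pi}{k^2} \sum_{n=1}^{N} (2n+1)\,
#'   \mathrm{Re}(a_n + b_n), \qquad k = 2\pi n_{med}/\lambda.}
#' The series is truncated at the Wiscombe criterion
#' \eqn{N = \lceil x + 4x^{1/3} + 2\rceil}; the logarithmic derivatives
#' of the Riccati-Bessel functions are generated by downward recurrence
#' started 15 orders above N.
#'
#' @param diameter_nm sphere diameter (nm).
#' @param wavelength_nm vacuum wavelength (nm).
#' @param m_particle complex refractive index of the particle
#'   (Im >= 0).
#' @param n_medium real refractive index of the host (>= 1).
#' @param components if `TRUE`, return a tibble with `cext` and `csca`
#'   (um^2) instead of the extinction vector.
#' @param n_terms optional override of the series truncation order
#'   (testing/convergence studies).
#' @return extinction cross section(s) in um^2 (or a tibble when
#'   `components = TRUE`).  Arguments are recycled to a common length.
#' @examples
#' mie_extinction(760, 500, complex(real = 1.39, imaginary = 1e-4), 1.335)
#' @export
mie_extinction <- function(diameter_nm, wavelength_nm, m_particle,
                           n_medium, components = FALSE, n_terms = NULL) {
  res <- mie_cross_sections(diameter_nm, wavelength_nm, m_particle,
                            n_medium, n_terms = n_terms)
  if (components) res else res$cext
}

# Core engine, vectorized over all arguments (recycled).
mie_cross_sections <- function(diameter_nm, wavelength_nm, m_particle,
                               n_medium, n_terms = NULL) {
  L <- max(length(diameter_nm), length(wavelength_nm),
           length(m_particle), length(n_medium))
  d <- rep_len(as.numeric(diameter_nm), L)
  lam <- rep_len(as.numeric(wavelength_nm), L)
  m <- rep_len(as.complex(m_particle), L)
  nmed <- rep_len(as.numeric(n_medium), L)
  if (any(!is.finite(d)) || any(!is.finite(lam)) ||
      any(!is.finite(Re(m))) || any(!is.finite(Im(m))) ||
      any(!is.finite(nmed))) {
    stop("non-finite Mie input", call. = FALSE)
  }
  if (any(d <= 0) || any(lam <= 0)) {
    stop("diameter and wavelength must be positive", call. = FALSE)
  }
  if (any(Im(m) < 0)) {
    stop("Im(m_particle) must be >= 0 (passive particle)", call. = FALSE)
  }
  if (any(nmed < 1)) stop("n_medium must be >= 1", call. = FALSE)
  x <- pi * d * nmed / lam
  if (any(x > 500)) {
    stop("size parameter x out of supported range (0, 500]", call. = FALSE)
  }
  mrel <- m / nmed
  mx <- mrel * x
  if (is.null(n_terms)) {
    nstop <- ceiling(x + 4 * x^(1 / 3) + 2)
  } else {
    nstop <- rep_len(as.integer(n_terms), L)
  }
  nmax <- max(nstop)
  nstart <- nmax + 15L

  # logarithmic derivative D_n(mx) by downward recurrence
  dmat <- matrix(0i, nrow = nmax, ncol = L)
  cur <- rep(0i, L)
  for (n in nstart:1) {
    rn <- n / mx
    prev <- rn - 1 / (cur + rn)
    if (n - 1L >= 1L && n - 1L <= nmax) dmat[n - 1L, ] <- prev
    cur <- prev
  }
  # store D_nmax too: recompute top entry (loop stored D_0..D_{nstart-1},
  # we captured 1..nmax-? ensure nmax row filled)
  # (rows 1..nmax-1 filled when n-1 in range; row nmax filled when
  #  n = nmax + 1, which is <= nstart, so it is filled.)

  psi_nm1 <- cos(x)  # psi_{-1}
  psi_n <- sin(x)    # psi_0
  chi_nm1 <- -sin(x) # chi_{-1}
  chi_n <- cos(x)    # chi_0
  xi_nm1 <- complex(real = psi_nm1, imaginary = -chi_nm1)
  xi_n <- complex(real = psi_n, imaginary = -chi_n)

  cext_sum <- numeric(L)
  csca_sum <- numeric(L)
  for (n in 1:nmax) {
    psi <- (2 * n - 1) / x * psi_n - psi_nm1
    chi <- (2 * n - 1) / x * chi_n - chi_nm1
    xi <- complex(real = psi, imaginary = -chi)
    dn <- dmat[n, ]
    fa <- dn / mrel + n / x
    fb <- dn * mrel + n / x
    an <- (fa * psi - psi_n) / (fa * xi - xi_n)
    bn <- (fb * psi - psi_n) / (fb * xi - xi_n)
    live <- n <= nstop
    if (!all(live)) {
      an[!live] <- 0i
      bn[!live] <- 0i
    }
    cext_sum <- cext_sum + (2 * n + 1) * Re(an + bn)
    csca_sum <- csca_sum + (2 * n + 1) * (Mod(an)^2 + Mod(bn)^2)
    psi_nm1 <- psi_n; psi_n <- psi
    chi_nm1 <- chi_n; chi_n <- chi
    xi_n <- xi
  }
  k <- 2 * pi * nmed / lam  # nm^-1
  pref <- 2 * pi / k^2      # nm^2
  tibble::tibble(cext = pref * cext_sum * 1e-6,  # nm^2 -> um^2
                 csca = pref * csca_sum * 1e-6)
}

#' Extinction spectrum of a single sphere
#'
#' Vectorizes [mie_extinction()] over the wavelength grid of a complex-RI
#' table.
#'
#' @param diameter_nm sphere diameter (nm).
#' @param ri an `hb_complex_ri` tibble (see [particle_complex_ri()]).
#' @param n_medium host refractive index: an `hb_spectrum` of kind
#'   `refractive_index` on the same grid, or `NULL` for pure water.
#' @return `hb_spectrum` of kind `extinction_cross_section` (um^2).
#' @export
mie_extinction_spectrum <- function(diameter_nm, ri, n_medium = NULL) {
  stopifnot(inherits(ri, "hb_complex_ri"))
  if (is.null(n_medium)) {
    n_medium <- water_ri(ri$wavelength_nm)
  }
  stopifnot(inherits(n_medium, "hb_spectrum"))
  if (length(n_medium$wavelength_nm) != nrow(ri) ||
      any(abs(n_medium$wavelength_nm - ri$wavelength_nm) > 1e-9)) {
    stop("`n_medium` grid must match the RI grid", call. = FALSE)
  }
  cext <- mie_extinction(diameter_nm, ri$wavelength_nm,
                         complex(real = ri$n, imaginary = ri$kappa),
                         n_medium$value)
  spectrum(ri$wavelength_nm, cext, "extinction_cross_section")
}
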