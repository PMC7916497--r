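#' Hemoglobin state mass fractions
#'
#' The three redox/ligation states of hemoglobin considered — oxygenated
#' (oxyHb), deoxygenated (deoxyHb) and methemoglobin (metHb) — are described
#' by mass fractions on the unit simplex.
#'
#' @param oxy,deoxy,met mass fractions in \[0, 1\]; must sum to 1 within
#'   1e-9.
#' @return A one-row tibble of class `hb_fractions` with columns
#'   `phi_oxy`, `phi_deoxy`, `phi_met`.
#' @examples
#' hb_fractions(0.65, 0, 0.35)
#' @export
hb_fractions <- function(oxy, deoxy, met) {
  v <- c(oxy = oxy, deoxy = deoxy, met = met)
  if (anyNA(v) || any(v < -1e-12) || any(v > 1 + 1e-12)) {
    stop("mass fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(v) - 1) > 1e-9) {
    stop("mass fractions must sum to 1 (got ", format(sum(v)), ")",
         call. = FALSE)
  }
  x <- tibble::tibble(phi_oxy = unname(pmin(pmax(oxy, 0), 1)),
                      phi_deoxy = unname(pmin(pmax(deoxy, 0), 1)),
                      phi_met = unname(pmin(pmax(met, 0), 1)))
  tibble::new_tibble(x, class = "hb_fractions")
}

#' Intra-particle protein composition
#'
#' Mass concentrations of total hemoglobin and of heme-free globin/HSA
#' inside a particle, plus the hemoglobin state fractions.  The reference
#' batch values are 120 g/L hemoglobin and 130 g/L globin/HSA, as obtained
#' from densitometry.
#'
#' @param beta_hb intra-particle total hemoglobin mass concentration (g/L).
#' @param beta_glhsa intra-particle heme-free globin/HSA mass
#'   concentration (g/L).
#' @param fractions an [hb_fractions()] row.
#' @return A list of class `particle_composition`.
#' @export
particle_composition <- function(beta_hb = 120, beta_glhsa = 130,
                                 fractions = hb_fractions(1, 0, 0)) {
  if (!is.numeric(beta_hb) || beta_hb < 0 ||
      !is.numeric(beta_glhsa) || beta_glhsa < 0) {
    stop("`beta_hb` and `beta_glhsa` must be non-negative (g/L)",
         call. = FALSE)
  }
  stopifnot(inherits(fractions, "hb_fractions"))
  structure(list(beta_hb = beta_hb, beta_glhsa = beta_glhsa,
                 fractions = fractions),
            class = "particle_composition")
}

#' Per-species optical increment tables
#'
#' Bundles the real refractive-index increment alpha(lambda) and the
#' imaginary increment gamma(lambda), both in mL/g, for one protein
#' species, together with the molar mass used to convert molar extinction
#' coefficients.
#'
#' @param species one of `"oxyHb"`, `"deoxyHb"`, `"metHb"`, `"GlHSA"`.
#' @param alpha `hb_spectrum` of kind `ri_increment_real` (mL/g).
#' @param gamma `hb_spectrum` of kind `ri_increment_imag` (mL/g).
#' @param molar_mass molar mass (g/mol) on the monomer basis; defaults to
#'   the hemoglobin monomer, 16114.5 g/mol.
#' @return A list of class `species_optics`.
#' @export
species_optics <- function(species, alpha, gamma,
                           molar_mass = hb_monomer_mass()) {
  species <- match.arg(species, c("oxyHb", "deoxyHb", "metHb", "GlHSA"))
  stopifnot(inherits(alpha, "hb_spectrum"), inherits(gamma, "hb_spectrum"))
  if (spectrum_kind(alpha) != "ri_increment_real" ||
      spectrum_kind(gamma) != "ri_increment_imag") {
    stop("`alpha` must be of kind ri_increment_real and `gamma` of kind ",
         "ri_increment_imag", call. = FALSE)
  }
  if (!same_grid(alpha, gamma)) {
    stop("`alpha` and `gamma` must share a common grid", call. = FALSE)
  }
  rng <- range(alpha$wavelength_nm)
  if (rng[1] > 300 || rng[2] < 800) {
    stop("species tables must cover at least 300-800 nm", call. = FALSE)
  }
  if (!is.numeric(molar_mass) || molar_mass <= 0) {
    stop("`molar_mass` must be > 0", call. = FALSE)
  }
  structure(list(species = species, alpha = alpha, gamma = gamma,
                 molar_mass = molar_mass),
            class = "species_optics")
}

#' Molar mass of the hemoglobin monomer
#'
#' One heme-bearing Hb(Fe) subunit: 16114.5 g/mol.
#' @return numeric scalar (g/mol).
#' @export
hb_monomer_mass <- function() 16114.5

#' Imaginary refractive-index increment from molar extinction
#'
#' Converts a molar (decadic) extinction coefficient spectrum to the
#' imaginary part of the specific refractive-index increment,
#' \deqn{\gamma(\lambda) = \frac{\ln 10\, \epsilon(\lambda)\, \lambda}
#'   {4\pi M},}
#' the only dimensionally consistent form linking the two.  Unit audit:
#' with epsilon in L mol^-1 cm^-1 = 10^3 cm^2/mol, lambda in cm and M in
#' g/mol, ln10 * eps * lambda / (4 pi M) has units cm^3/g = mL/g; carrying
#' lambda in nm instead introduces the factor 1e-7 cm/nm, and the leading
#' 10^3 of the litre gives the net 1e-4 used below.
#'
#' @param epsilon `hb_spectrum` of kind `molar_extinction`
#'   (L mol^-1 cm^-1).
#' @param molar_mass molar mass (g/mol) of the absorbing unit.
#' @return `hb_spectrum` of kind `ri_increment_imag` (mL/g) on the same
#'   grid.
#' @examples
#' eps <- spectrum(574, 6945, "molar_extinction")
#' gamma_from_epsilon(eps, 16114.5)$value  # ~4.53e-3 mL/g
#' @export
gamma_from_epsilon <- function(epsilon, molar_mass = hb_monomer_mass()) {
  stopifnot(inherits(epsilon, "hb_spectrum"))
  if (spectrum_kind(epsilon) != "molar_extinction") {
    stop("`epsilon` must be a spectrum of kind molar_extinction",
         call. = FALSE)
  }
  if (!is.numeric(molar_mass) || length(molar_mass) != 1 ||
      !is.finite(molar_mass) || molar_mass <= 0) {
    stop("`molar_mass` must be a positive number", call. = FALSE)
  }
  if (any(epsilon$value < 0)) {
    stop("molar extinction values must be >= 0", call. = FALSE)
  }
  g <- 1e-4 * log(10) * epsilon$value * epsilon$wavelength_nm /
    (4 * pi * molar_mass)
  new_spectrum_like(epsilon, g, "ri_increment_imag")
}

#' Molar extinction from an imaginary increment
#'
#' Exact inverse of [gamma_from_epsilon()].
#'
#' @param gamma `hb_spectrum` of kind `ri_increment_imag` (mL/g).
#' @param molar_mass molar mass (g/mol).
#' @return `hb_spectrum` of kind `molar_extinction` (L mol^-1 cm^-1).
#' @export
epsilon_from_gamma <- function(gamma, molar_mass = hb_monomer_mass()) {
  stopifnot(inherits(gamma, "hb_spectrum"))
  if (spectrum_kind(gamma) != "ri_increment_imag") {
    stop("`gamma` must be a spectrum of kind ri_increment_imag",
         call. = FALSE)
  }
  e <- gamma$value * (4 * pi * molar_mass) /
    (1e-4 * log(10) * gamma$wavelength_nm)
  new_spectrum_like(gamma, e, "molar_extinction")
}

#' Refractive index of pure water
#'
#' Empirical four-term Sellmeier dispersion formula for pure water
#' (Daimon & Masumura 2007 coefficients, valid 182-1129 nm, near the
#' 23 degC density-measurement temperature used package-wide).  Normal
#' dispersion: monotonically decreasing over 300-800 nm.
#'
#' @param wavelength_nm vacuum wavelengths (nm) within 200-1100 nm.
#' @return `hb_spectrum` of kind `refractive_index`.
#' @examples
#' water_ri(589)$value  # ~1.333
#' @export
water_ri <- function(wavelength_nm) {
  if (any(wavelength_nm < 200 | wavelength_nm > 1100)) {
    stop("water RI dispersion formula is applied only for 200-1100 nm",
         call. = FALSE)
  }
  l2 <- (wavelength_nm / 1000)^2  # um^2
  b <- c(5.684027565e-1, 1.726177391e-1, 2.086189578e-2, 1.130748688e-1)
  cc <- c(5.101829712e-3, 1.821153936e-2, 2.620722293e-2, 1.069792721e1)
  n2 <- 1 + l2 * (b[1] / (l2 - cc[1]) + b[2] / (l2 - cc[2]) +
                    b[3] / (l2 - cc[3]) + b[4] / (l2 - cc[4]))
  spectrum(wavelength_nm, sqrt(n2), "refractive_index")
}

#' Subtractive Kramers-Kronig transform of an increment difference
#'
#' Derives the real refractive-index increment of a target species from a
#' reference species whose real increment is known, using the
#' Kramers-Kronig (KK) relation applied to the *difference* of the
#' imaginary increments.  In wavelength form the causality relation reads
#' \deqn{\Delta\alpha(\lambda) = \frac{2}{\pi}\,\mathrm{P}\!\!\int
#'   \frac{\Delta\gamma(\lambda')\,\lambda^2}
#'        {\lambda'\,(\lambda^2 - \lambda'^2)}\, d\lambda',}
#' and \eqn{\alpha_{target} = \alpha_{ref} + \Delta\alpha}.  Working on
#' the difference (singly subtractive form) confines the integrand to the
#' absorption bands that actually differ, so a finite tabulated grid
#' suffices.
#'
#' Numerics: principal-value trapezoidal quadrature with the pole removed
#' by subtracting the integrand value at the pole; the excised node is
#' replaced by the analytic limit (numerical derivative) and the boundary
#' log term of the subtracted kernel is added back.  The grid must extend
#' at least `pad_nm` beyond both ends of the 300-800 nm output window.
#'
#' @param gamma_target,gamma_ref `hb_spectrum`s of kind
#'   `ri_increment_imag` on a common grid.
#' @param alpha_ref `hb_spectrum` of kind `ri_increment_real` on the same
#'   grid.
#' @param output_range numeric length-2, wavelength window (nm) of the
#'   returned spectrum; default `c(300, 800)`.
#' @param pad_nm minimum grid padding (nm) required beyond each end of
#'   `output_range`; insufficient padding raises a warning (escalate with
#'   `strict_pad = TRUE`).
#' @param strict_pad logical; treat insufficient padding as an error.
#' @return `hb_spectrum` of kind `ri_increment_real` restricted to
#'   `output_range`.
#' @export
kk_real_increment <- function(gamma_target, gamma_ref, alpha_ref,
                              output_range = c(300, 800), pad_nm = 50,
                              strict_pad = FALSE) {
  stopifnot(inherits(gamma_target, "hb_spectrum"),
            inherits(gamma_ref, "hb_spectrum"),
            inherits(alpha_ref, "hb_spectrum"))
  if (!same_grid(gamma_target, gamma_ref) ||
      !same_grid(gamma_target, alpha_ref)) {
    stop("all three spectra must share a common wavelength grid",
         call. = FALSE)
  }
  lam <- gamma_target$wavelength_nm
  if (lam[1] > output_range[1] - pad_nm ||
      lam[length(lam)] < output_range[2] + pad_nm) {
    msg <- sprintf(
      "grid should extend at least %g nm beyond [%g, %g] on both sides",
      pad_nm, output_range[1], output_range[2])
    if (strict_pad) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  dgam <- gamma_target$value - gamma_ref$value
  out_idx <- which(lam >= output_range[1] & lam <= output_range[2])
  if (length(out_idx) == 0L) {
    stop("no grid points inside the output range", call. = FALSE)
  }
  dalpha <- vapply(out_idx, function(i) kk_pv_at(lam, dgam, i), numeric(1))
  alpha <- alpha_ref$value[out_idx] + dalpha
  spectrum(lam[out_idx], alpha, "ri_increment_real")
}

# Principal-value KK integral at grid node i.
# Integrand: dgam(l') * l^2 / (l' (l^2 - l'^2)) = h(l') / (l - l'),
# with h(l') = dgam(l') * l^2 / (l' (l + l')).
kk_pv_at <- function(lam, dgam, i) {
  l0 <- lam[i]
  h <- dgam * l0^2 / (lam * (l0 + lam))
  # h at the pole and its derivative (central difference where possible)
  n <- length(lam)
  i_lo <- max(i - 1L, 1L)
  i_hi <- min(i + 1L, n)
  hprime <- (h[i_hi] - h[i_lo]) / (lam[i_hi] - lam[i_lo])
  q <- (h - h[i]) / (l0 - lam)
  q[i] <- -hprime
  integral <- trapz(lam, q)
  # boundary term of P int_a^b dl'/(l0 - l') = ln((l0 - a)/(b - l0))
  a <- lam[1]; b <- lam[n]
  bound <- if (l0 > a && l0 < b) log((l0 - a) / (b - l0)) else 0
  (2 / pi) * (integral + h[i] * bound)
}

trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Complex refractive index of a hemoglobin microparticle
#'
#' Superposes the species refractive-index increments onto the host-water
#' refractive index:
#' \deqn{n(\lambda) + i\kappa(\lambda) = n_{H_2O}(\lambda)
#'   + \beta_{Hb}\,[\alpha_{Hb} + i\gamma_{Hb}]
#'   + \beta_{Gl/HSA}\,[\alpha_{HSA} + i\gamma_{HSA}],}
#' where the hemoglobin increments are the fraction-weighted sums over
#' oxyHb, deoxyHb and metHb.  Concentrations are supplied in g/L and
#' converted to g/mL to match increments in mL/g.
#'
#' @param composition a [particle_composition()].
#' @param optics named list of [species_optics()] containing `oxyHb`,
#'   `deoxyHb`, `metHb` and `GlHSA`; default [hb_default_optics()].
#' @param wavelength_nm evaluation grid (nm) inside the species-table
#'   range.
#' @return tibble of class `hb_complex_ri` with columns `wavelength_nm`,
#'   `n`, `kappa`.
#' @examples
#' ri <- particle_complex_ri(
#'   particle_composition(120, 130, hb_fractions(0.65, 0, 0.35)),
#'   wavelength_nm = 488)
#' @export
particle_complex_ri <- function(composition, optics = hb_default_optics(),
                                wavelength_nm = seq(300, 800, by = 5)) {
  stopifnot(inherits(composition, "particle_composition"))
  needed <- c("oxyHb", "deoxyHb", "metHb", "GlHSA")
  if (!all(needed %in% names(optics))) {
    stop("`optics` must contain species tables for ",
         paste(setdiff(needed, names(optics)), collapse = ", "),
         call. = FALSE)
  }
  f <- composition$fractions
  grab <- function(sp, which) {
    spectrum_interp(optics[[sp]][[which]], wavelength_nm)$value
  }
  alpha_hb <- f$phi_oxy * grab("oxyHb", "alpha") +
    f$phi_deoxy * grab("deoxyHb", "alpha") +
    f$phi_met * grab("metHb", "alpha")
  gamma_hb <- f$phi_oxy * grab("oxyHb", "gamma") +
    f$phi_deoxy * grab("deoxyHb", "gamma") +
    f$phi_met * grab("metHb", "gamma")
  alpha_hsa <- grab("GlHSA", "alpha")
  gamma_hsa <- grab("GlHSA", "gamma")
  b_hb <- composition$beta_hb / 1000    # g/L -> g/mL
  b_gl <- composition$beta_glhsa / 1000
  n_w <- water_ri(wavelength_nm)$value
  out <- tibble::tibble(
    wavelength_nm = as.numeric(wavelength_nm),
    n = n_w + b_hb * alpha_hb + b_gl * alpha_hsa,
    kappa = b_hb * gamma_hb + b_gl * gamma_hsa)
  tibble::new_tibble(out, class = "hb_complex_ri")
}
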