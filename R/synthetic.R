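#' Gaussian band model for a molar extinction spectrum
#'
#' Stand-in for tabulated literature extinction spectra: a sum of
#' Gaussian bands \eqn{\epsilon(\lambda) = \sum_k A_k
#'   \exp[-(\lambda-c_k)^2/(2 s_k^2)] + b} with a small positive
#' baseline.  Not authoritative data — a pluggable synthetic model whose
#' band positions follow the known hemoglobin features (Soret band near
#' 400-430 nm, Q bands near 540-580 nm, the metHb marker near 640 nm).
#'
#' @param center_nm band centers (nm).
#' @param width_nm Gaussian standard deviations (nm), > 0.
#' @param peak peak molar extinction coefficients, non-negative
#'   (L mol^-1 cm^-1).
#' @param baseline constant offset (L mol^-1 cm^-1), >= 0.
#' @return tibble of class `hb_band_model` with attribute `baseline`.
#' @export
band_model <- function(center_nm, width_nm, peak, baseline = 0) {
  if (length(center_nm) != length(width_nm) ||
      length(center_nm) != length(peak)) {
    stop("band vectors must have equal length", call. = FALSE)
  }
  if (any(width_nm <= 0)) stop("band widths must be > 0", call. = FALSE)
  if (any(peak < 0) || baseline < 0) {
    stop("band peaks and baseline must be >= 0", call. = FALSE)
  }
  x <- tibble::tibble(center_nm = as.numeric(center_nm),
                      width_nm = as.numeric(width_nm),
                      peak = as.numeric(peak))
  tibble::new_tibble(x, baseline = baseline, class = "hb_band_model")
}

band_model_epsilon <- function(bm, wavelength_nm) {
  eps <- rep(attr(bm, "baseline", exact = TRUE), length(wavelength_nm))
  for (i in seq_len(nrow(bm))) {
    eps <- eps + bm$peak[i] *
      exp(-(wavelength_nm - bm$center_nm[i])^2 / (2 * bm$width_nm[i]^2))
  }
  eps
}

#' Default band models for the four species
#'
#' OxyHb: Soret at 413 nm plus Q bands at 543/578 nm; deoxyHb: single
#' Soret at 430 nm plus its Q band; metHb: Soret at 409 nm, a broad
#' green feature and the 640 nm marker; Gl/HSA: no visible-range bands.
#' A broad low-amplitude component around 490 nm keeps the inter-band
#' valley at a realistic level for the heme species.  Amplitudes give
#' order-of-magnitude realistic Soret/Q ratios (~10:1).
#'
#' @return named list of [band_model()]s.
#' @export
default_band_models <- function() {
  list(
    oxyHb = band_model(c(413, 543, 578, 490),
                       c(16, 11, 9, 90),
                       c(128000, 14000, 15500, 5200), baseline = 50),
    deoxyHb = band_model(c(430, 555, 490),
                         c(16, 14, 90),
                         c(133000, 13500, 5200), baseline = 50),
    metHb = band_model(c(409, 500, 640),
                       c(14, 40, 15),
                       c(120000, 9000, 3900), baseline = 50),
    GlHSA = band_model(numeric(0), numeric(0), numeric(0), baseline = 0)
  )
}

#' Build a species optics table from a band model
#'
#' Generates the molar extinction spectrum from the band model, converts
#' it to the imaginary increment via [gamma_from_epsilon()], and derives
#' the real increment by the subtractive Kramers-Kronig transform
#' against a flat reference increment (`alpha_baseline`, the
#' non-dispersive specific refraction of the protein) with zero
#' reference absorption.  The grid must extend beyond 300-800 nm on both
#' sides to pad the principal-value integral.
#'
#' @param species `"oxyHb"`, `"deoxyHb"`, `"metHb"` or `"GlHSA"`.
#' @param bands a [band_model()]; default from [default_band_models()].
#' @param grid wavelength grid (nm) covering at least 250-850 nm.
#' @param alpha_baseline flat real increment (mL/g); defaults to 0.200
#'   for the heme species and 0.185 for Gl/HSA.
#' @param molar_mass molar mass used in the extinction conversion;
#'   defaults to the Hb monomer for heme species and 66437 g/mol for
#'   Gl/HSA.
#' @return a [species_optics()] on the 300-800 nm portion of `grid`.
#' @export
make_species_optics <- function(species, bands = NULL,
                                grid = seq(250, 850, by = 1),
                                alpha_baseline = NULL,
                                molar_mass = NULL) {
  species <- match.arg(species, c("oxyHb", "deoxyHb", "metHb", "GlHSA"))
  if (min(grid) > 250 || max(grid) < 850) {
    stop("grid must cover 250-850 nm (padding for Kramers-Kronig)",
         call. = FALSE)
  }
  if (is.null(bands)) bands <- default_band_models()[[species]]
  stopifnot(inherits(bands, "hb_band_model"))
  if (is.null(alpha_baseline)) {
    alpha_baseline <- if (species == "GlHSA") 0.185 else 0.200
  }
  if (is.null(molar_mass)) {
    molar_mass <- if (species == "GlHSA") 66437 else hb_monomer_mass()
  }
  eps <- spectrum(grid, band_model_epsilon(bands, grid),
                  "molar_extinction")
  gam <- gamma_from_epsilon(eps, molar_mass)
  zero_gam <- new_spectrum_like(gam, rep(0, nrow(gam)),
                                "ri_increment_imag")
  flat_alpha <- new_spectrum_like(gam, rep(alpha_baseline, nrow(gam)),
                                  "ri_increment_real")
  alpha <- kk_real_increment(gam, zero_gam, flat_alpha)
  gam_win <- spectrum_window(gam, min(alpha$wavelength_nm),
                             max(alpha$wavelength_nm))
  species_optics(species, alpha, gam_win, molar_mass)
}

the_optics_cache <- new.env(parent = emptyenv())

#' Default synthetic optics for all four species
#'
#' Builds (and memoises) the species optics tables from
#' [default_band_models()] on a common 250-850 nm grid.  These are
#' synthetic stand-ins for literature increment tables; substitute
#' authoritative tables via [read_species_optics()] for real analyses.
#'
#' @param grid wavelength grid (nm) covering 250-850 nm; default 1 nm
#'   steps.
#' @return named list of [species_optics()].
#' @export
hb_default_optics <- function(grid = seq(250, 850, by = 1)) {
  key <- paste0("g", min(grid), "_", max(grid), "_", length(grid))
  if (!is.null(the_optics_cache[[key]])) return(the_optics_cache[[key]])
  out <- lapply(stats::setNames(nm = c("oxyHb", "deoxyHb", "metHb",
                                       "GlHSA")),
                make_species_optics, grid = grid)
  the_optics_cache[[key]] <- out
  out
}

#' Synthesize a transmittance measurement from the forward model
#'
#' Inverse of the volume-specific extinction conversion:
#' \eqn{T(\lambda) = \exp(-\ell\,PPV\,\varphi\,Z(\lambda))} from the
#' forward-model Z, with optional multiplicative log-normal photometric
#' noise on T.  Deterministic for a fixed seed; the noiseless spectrum
#' round-trips through [transmittance_to_vsecs()] exactly.
#'
#' @param fractions an [hb_fractions()] row.
#' @param psd an `hb_psd`.
#' @param composition_base a [particle_composition()].
#' @param instrument list with `path_mm`, `volume_fraction`, `ppv`;
#'   defaults are the reference cuvette (10 mm) with the working
#'   dilution (5.58e-4) and stock PPV 0.1992.
#' @param noise_sigma standard deviation of the log-normal multiplicative
#'   noise on T (0 = noiseless).
#' @param seed integer seed, mandatory when `noise_sigma > 0`.
#' @param optics named list of [species_optics()].
#' @param wavelength_nm evaluation grid (nm).
#' @param d_step diameter quadrature step (nm).
#' @return a [transmittance_measurement()].
#' @export
synthesize_transmittance <- function(fractions, psd,
                                     composition_base =
                                       particle_composition(),
                                     instrument = list(
                                       path_mm = 10,
                                       volume_fraction = 5.58e-4,
                                       ppv = 0.1992),
                                     noise_sigma = 0, seed = NULL,
                                     optics = hb_default_optics(),
                                     wavelength_nm = seq(300, 800, by = 5),
                                     d_step = 10) {
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (noise_sigma > 0 && is.null(seed)) {
    stop("`seed` is mandatory when `noise_sigma` > 0", call. = FALSE)
  }
  z <- forward_vsecs(fractions, psd, composition_base, optics,
                     wavelength_nm, d_step)
  ell_um <- instrument$path_mm * 1000
  tvals <- exp(-ell_um * instrument$ppv * instrument$volume_fraction *
                 z$value)
  if (any(tvals > 1 + 1e-12)) {
    stop("instrument parameters yield transmittance > 1", call. = FALSE)
  }
  if (noise_sigma > 0) {
    tvals <- with_local_seed(seed, {
      pmin(tvals * exp(stats::rnorm(length(tvals), 0, noise_sigma)), 1)
    })
  }
  transmittance_measurement(
    spectrum(wavelength_nm, tvals, "transmittance"),
    path_length_mm = instrument$path_mm,
    volume_fraction = instrument$volume_fraction,
    ppv = instrument$ppv)
}

#' Synthesize a dilution series
#'
#' One synthetic measurement per volume fraction, sharing one seed
#' stream.  The default volume fractions emulate pipetting 10-670 uL of
#' a 100-fold pre-diluted stock into a 2.2 mL cuvette (six dilutions).
#' Optionally a multiple-scattering artefact — a saturating nonlinearity
#' that fills in transmitted light at strong extinction — is injected
#' into members whose transmittance drops below `ms_threshold`, so that
#' dilution-QC logic can be exercised.
#'
#' @inheritParams synthesize_transmittance
#' @param phis increasing vector of volume fractions; default the
#'   six-step series described above.
#' @param multiple_scattering logical, inject the artefact (default
#'   `FALSE`).
#' @param ms_threshold transmittance below which the artefact acts.
#' @param ms_strength strength of the saturating nonlinearity.
#' @return list of [transmittance_measurement()]s, ordered as `phis`.
#' @export
make_dilution_series <- function(fractions, psd,
                                 composition_base =
                                   particle_composition(),
                                 phis = dilution_series_phis(),
                                 instrument = list(path_mm = 10,
                                                   ppv = 0.1992),
                                 noise_sigma = 0, seed = NULL,
                                 multiple_scattering = FALSE,
                                 ms_threshold = 0.30,
                                 ms_strength = 0.15,
                                 optics = hb_default_optics(),
                                 wavelength_nm = seq(300, 800, by = 5),
                                 d_step = 10) {
  if (any(diff(phis) <= 0) || any(phis <= 0)) {
    stop("`phis` must be positive and increasing", call. = FALSE)
  }
  z <- forward_vsecs(fractions, psd, composition_base, optics,
                     wavelength_nm, d_step)
  ell_um <- instrument$path_mm * 1000
  out <- vector("list", length(phis))
  for (i in seq_along(phis)) {
    tvals <- exp(-ell_um * instrument$ppv * phis[i] * z$value)
    if (multiple_scattering && min(tvals) < ms_threshold) {
      # forward-scattered light partially fills in the beam at strong
      # extinction: observed |ln T| is reduced where T is low
      tvals <- exp(log(tvals) * (1 - ms_strength * (1 - tvals)))
    }
    if (noise_sigma > 0) {
      if (is.null(seed)) stop("`seed` is mandatory when `noise_sigma` > 0",
                              call. = FALSE)
      tvals <- with_local_seed(seed + i, {
        pmin(tvals * exp(stats::rnorm(length(tvals), 0, noise_sigma)), 1)
      })
    }
    out[[i]] <- transmittance_measurement(
      spectrum(wavelength_nm, tvals, "transmittance"),
      path_length_mm = instrument$path_mm, volume_fraction = phis[i],
      ppv = instrument$ppv)
  }
  out
}

#' Default dilution-series volume fractions
#'
#' Volume fractions of stock suspension obtained by pipetting the given
#' sample volumes of a 100-fold pre-diluted stock into a 2.2 mL cuvette:
#' phi = (v / (2200 + v)) / 100.
#'
#' @param volumes_ul pipetted volumes (uL).
#' @param cuvette_ul cuvette fill volume (uL).
#' @param predilution pre-dilution factor of the stock.
#' @return numeric vector of volume fractions.
#' @export
dilution_series_phis <- function(volumes_ul = c(10, 30, 70, 130, 300, 670),
                                 cuvette_ul = 2200, predilution = 100) {
  (volumes_ul / (cuvette_ul + volumes_ul)) / predilution
}

# evaluate `expr` under a temporary RNG state, restoring the caller's
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(),
                     inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
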