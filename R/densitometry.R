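#' Density panel of a particle suspension
#'
#' Measured densities of the stock suspension, its supernatant and the
#' diluent (acetated Ringer's solution), the packed particle volume
#' (PPV) and the density increments of the two protein classes.  The
#' density increment of a solute is the derivative of solution density
#' with respect to solute mass concentration,
#' \eqn{DI = \partial\rho/\partial\beta} (dimensionless when rho is in
#' g/mL and beta in g/mL).
#'
#' Defaults are the reference batch panel: rho_sus 1.01639, rho_sup
#' 1.00422, rho_RAc 1.00320 g/mL, PPV 0.1992, DI_Hb 0.2450 (bovine Hb),
#' DI_Gl/HSA 0.2505.
#'
#' @param rho_sus,rho_sup,rho_rac densities (g/mL) of suspension,
#'   supernatant and acetated Ringer's solution; plausible aqueous range
#'   (0.9, 1.2).
#' @param ppv packed particle volume, in (0, 1).
#' @param di_hb,di_glhsa density increments, in (0, 1).
#' @return list of class `density_panel`.
#' @export
density_panel <- function(rho_sus = 1.01639, rho_sup = 1.00422,
                          rho_rac = 1.00320, ppv = 0.1992,
                          di_hb = 0.2450, di_glhsa = 0.2505) {
  dens <- c(rho_sus = rho_sus, rho_sup = rho_sup, rho_rac = rho_rac)
  if (any(dens <= 0.9 | dens >= 1.2)) {
    stop("densities must lie in (0.9, 1.2) g/mL", call. = FALSE)
  }
  if (ppv <= 0 || ppv >= 1) stop("`ppv` must lie in (0, 1)", call. = FALSE)
  if (di_hb <= 0 || di_hb >= 1 || di_glhsa <= 0 || di_glhsa >= 1) {
    stop("density increments must lie in (0, 1)", call. = FALSE)
  }
  structure(list(rho_sus = rho_sus, rho_sup = rho_sup, rho_rac = rho_rac,
                 ppv = ppv, di_hb = di_hb, di_glhsa = di_glhsa),
            class = "density_panel")
}

#' Ensemble density of the particles
#'
#' \deqn{\rho_{P} = \frac{1}{PPV}(\rho_{sus} - \rho_{sup}) + \rho_{sup}.}
#'
#' @param panel a [density_panel()].
#' @return density in g/mL.
#' @examples
#' particle_density(density_panel())  # 1.0653 g/mL
#' @export
particle_density <- function(panel) {
  stopifnot(inherits(panel, "density_panel"))
  (panel$rho_sus - panel$rho_sup) / panel$ppv + panel$rho_sup
}

#' Heme-free globin/HSA concentration in the stock suspension
#'
#' Solves the density-increment balance
#' \eqn{\rho_{sus} - \rho_{RAc} = DI_{Hb}\beta_{Hb} +
#'   DI_{Gl/HSA}\beta_{Gl/HSA}} for the heme-free protein concentration.
#' Densities (g/mL) are converted to g/L at this single boundary so that
#' all mass concentrations are in g/L.
#'
#' @param panel a [density_panel()].
#' @param beta_hb_sus total hemoglobin concentration in the stock
#'   suspension (g/L).
#' @return heme-free globin/HSA concentration (g/L).
#' @examples
#' glhsa_in_suspension(density_panel(), 25.5)  # 27.7 g/L
#' @export
glhsa_in_suspension <- function(panel, beta_hb_sus) {
  stopifnot(inherits(panel, "density_panel"))
  out <- ((panel$rho_sus - panel$rho_rac) * 1000 -
            panel$di_hb * beta_hb_sus) / panel$di_glhsa
  if (out < 0) {
    stop("density difference smaller than the Hb contribution: ",
         "inconsistent panel / beta_hb_sus", call. = FALSE)
  }
  out
}

#' Hemoglobin concentration in the supernatant
#'
#' Applies the same density-increment balance to the supernatant under
#' the assumption that the Gl/HSA-to-Hb mass ratio in the supernatant
#' equals that of the suspension:
#' \deqn{\beta_{Hb}^{sup} = \frac{\rho_{sup} - \rho_{RAc}}
#'   {DI_{Hb} + DI_{Gl/HSA}\,r}, \qquad
#'   r = \beta_{Gl/HSA}^{sus}/\beta_{Hb}^{sus}.}
#'
#' @param panel a [density_panel()].
#' @param ratio_glhsa_hb Gl/HSA-to-Hb mass ratio, >= 0.
#' @return hemoglobin concentration in the supernatant (g/L).
#' @export
hb_in_supernatant <- function(panel, ratio_glhsa_hb) {
  stopifnot(inherits(panel, "density_panel"))
  if (ratio_glhsa_hb < 0) stop("`ratio_glhsa_hb` must be >= 0",
                               call. = FALSE)
  denom <- panel$di_hb + panel$di_glhsa * ratio_glhsa_hb
  if (denom <= 0) stop("zero denominator in supernatant balance",
                       call. = FALSE)
  (panel$rho_sup - panel$rho_rac) * 1000 / denom
}

#' Hemoglobin concentration inside the particles
#'
#' Mass balance over the suspension,
#' \eqn{\beta_{Hb}^{sus} = PPV\,\beta_{Hb}^{P} +
#'   (1-PPV)\,\beta_{Hb}^{sup}}, solved for the intra-particle
#' concentration.
#'
#' @param beta_hb_sus,beta_hb_sup hemoglobin concentrations (g/L) in the
#'   suspension and the supernatant; feed unrounded values when chaining.
#' @param ppv packed particle volume, > 0.
#' @return intra-particle hemoglobin concentration (g/L).
#' @export
hb_in_particles <- function(beta_hb_sus, beta_hb_sup, ppv) {
  if (ppv <= 0) stop("`ppv` must be > 0", call. = FALSE)
  out <- (beta_hb_sus - (1 - ppv) * beta_hb_sup) / ppv
  if (out < 0) {
    stop("negative intra-particle concentration: inconsistent inputs",
         call. = FALSE)
  }
  out
}

#' Chained density-composition solve
#'
#' Runs the full chain — heme-free protein in suspension, hemoglobin in
#' supernatant, hemoglobin inside the particles — without intermediate
#' rounding (the printed-table values are only reproduced on the
#' unrounded chain; round at the reporting layer).  The
#' constant-Gl/HSA-to-Hb-ratio assumption is recorded in the output.
#'
#' @param panel a [density_panel()].
#' @param beta_hb_sus measured total hemoglobin concentration in the
#'   stock suspension (g/L).
#' @return one-row tibble with the solved concentrations (g/L), the
#'   Gl/HSA-to-Hb ratio, the particle density (g/mL) and the assumption
#'   flag.
#' @examples
#' solve_composition(density_panel(), 25.5)
#' @export
solve_composition <- function(panel, beta_hb_sus) {
  stopifnot(inherits(panel, "density_panel"))
  beta_gl_sus <- glhsa_in_suspension(panel, beta_hb_sus)
  ratio <- beta_gl_sus / beta_hb_sus
  beta_hb_sup <- hb_in_supernatant(panel, ratio)
  beta_hb_p <- hb_in_particles(beta_hb_sus, beta_hb_sup, panel$ppv)
  tibble::tibble(
    beta_hb_sus = beta_hb_sus,
    beta_glhsa_sus = beta_gl_sus,
    ratio_glhsa_hb = ratio,
    beta_hb_sup = beta_hb_sup,
    beta_hb_hbmp = beta_hb_p,
    beta_glhsa_hbmp = ratio * beta_hb_p,
    rho_hbmp = particle_density(panel),
    assumes_equal_ratio_in_supernatant = TRUE)
}

#' Particle concentration from PPV and median diameter
#'
#' \deqn{C_0 = \frac{PPV}{(4/3)\pi (D_{median}/2)^3}}
#' with the sphere-equivalent median diameter; reported in particles per
#' picoliter (1 pL = 10^3 um^3).
#'
#' @param ppv packed particle volume.
#' @param median_diameter_nm sphere-equivalent median diameter (nm), > 0.
#' @return concentration in pL^-1.
#' @examples
#' particle_concentration(0.1992, 760)  # ~866.7 pL^-1
#' @export
particle_concentration <- function(ppv, median_diameter_nm) {
  if (median_diameter_nm <= 0) stop("diameter must be > 0", call. = FALSE)
  v_um3 <- pi / 6 * (median_diameter_nm * 1e-3)^3
  ppv / v_um3 * 1e3
}

#' Total hemoglobin by the alkaline haematin detergent (AHD) assay
#'
#' Photometric total-Hb determination after enzymatic digestion:
#' \deqn{\beta_{Hb}^{sus} = \frac{A(\lambda)\, M}{\ell\, \epsilon(\lambda)
#'   \,\varphi_i}}
#' per dilution, with the AHD chromophore extinction
#' \eqn{\epsilon(574\,nm) = 6945} L mol^-1 cm^-1 and the hemoglobin
#' monomer mass by default.  Multiple dilutions are combined by a
#' weighted average (inverse-variance when per-dilution uncertainties
#' are supplied, otherwise equal weights).
#'
#' @param absorbance absorbance value(s) at the analysis wavelength.
#' @param dilution volume fraction(s) of the digested sample, in (0, 1].
#' @param path_length_cm cuvette path length (cm), default 1.
#' @param epsilon molar extinction coefficient (L mol^-1 cm^-1).
#' @param molar_mass molar mass of the monomer (g/mol).
#' @param u optional per-dilution standard uncertainties of the
#'   concentration (g/L) for inverse-variance weighting.
#' @return total hemoglobin concentration (g/L); per-dilution values are
#'   attached as attribute `"per_dilution"`.
#' @examples
#' total_hb_ahd(0.5, 0.116)  # ~10 g/L
#' @export
total_hb_ahd <- function(absorbance, dilution, path_length_cm = 1,
                         epsilon = 6945, molar_mass = hb_monomer_mass(),
                         u = NULL) {
  if (any(absorbance < 0)) stop("absorbance must be >= 0", call. = FALSE)
  if (any(dilution <= 0 | dilution > 1)) {
    stop("`dilution` must lie in (0, 1]", call. = FALSE)
  }
  beta_i <- absorbance * molar_mass /
    (path_length_cm * epsilon * dilution)
  w <- if (is.null(u)) rep(1, length(beta_i)) else 1 / u^2
  out <- sum(w * beta_i) / sum(w)
  attr(out, "per_dilution") <- tibble::tibble(
    absorbance = absorbance, dilution = dilution, beta_gL = beta_i)
  out
}

#' Functional-hemoglobin summary of a particle batch
#'
#' Combines the intra-particle hemoglobin concentration, the
#' Gl/HSA-to-Hb ratio and the metHb mass fraction into the functional
#' (non-met) hemoglobin concentration and its fraction of the total
#' protein:
#' functional = (1 - phi_met) * beta_Hb;  Gl/HSA = ratio * beta_Hb;
#' fraction = functional / (beta_Hb + Gl/HSA).
#'
#' @param beta_hb_hbmp intra-particle hemoglobin concentration (g/L).
#' @param ratio_glhsa_hb Gl/HSA-to-Hb mass ratio.
#' @param phi_met metHb mass fraction, in \[0, 1\].
#' @return one-row tibble with `functional_hb_gL`, `glhsa_hbmp_gL`,
#'   `total_protein_gL`, `functional_fraction`.
#' @examples
#' functional_summary(120.1, 1.0868, 0.35)  # ~78 g/L, ~31%
#' @export
functional_summary <- function(beta_hb_hbmp, ratio_glhsa_hb, phi_met) {
  if (phi_met < 0 || phi_met > 1) {
    stop("`phi_met` must lie in [0, 1]", call. = FALSE)
  }
  functional <- (1 - phi_met) * beta_hb_hbmp
  glhsa <- ratio_glhsa_hb * beta_hb_hbmp
  tibble::tibble(functional_hb_gL = functional,
                 glhsa_hbmp_gL = glhsa,
                 total_protein_gL = beta_hb_hbmp + glhsa,
                 functional_fraction = functional /
                   (beta_hb_hbmp + glhsa))
}

#' Relative non-functional hemoglobin
#'
#' Percentage of the total hemoglobin that is not functional,
#' \eqn{100\,(1 - \beta_{functional}/\beta_{total})}; report rounded to
#' the nearest integer percent.
#'
#' @param functional_meas functional hemoglobin concentration (g/L).
#' @param total_hb total hemoglobin concentration (g/L), > 0.
#' @param digits optional rounding for reporting (e.g. 0 for integer
#'   percent); `NULL` returns the unrounded value.
#' @return percentage.
#' @examples
#' relative_nonfunctional(11.8, 25.5, digits = 0)  # 54
#' @export
relative_nonfunctional <- function(functional_meas, total_hb,
                                   digits = NULL) {
  if (total_hb <= 0) stop("`total_hb` must be > 0", call. = FALSE)
  if (functional_meas < 0 || functional_meas > total_hb) {
    stop("`functional_meas` must lie in [0, total_hb]", call. = FALSE)
  }
  out <- 100 * (1 - functional_meas / total_hb)
  if (!is.null(digits)) out <- round(out, digits)
  out
}
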