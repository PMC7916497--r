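#' Simplex grid of hemoglobin state fractions
#'
#' All compositions (phi_oxy, phi_deoxy, phi_met) on a regular grid of
#' the unit 2-simplex.
#'
#' @param step grid step (default 0.025); 1/step must be close to an
#'   integer.
#' @return tibble with columns `phi_oxy`, `phi_deoxy`, `phi_met`.
#' @export
simplex_grid <- function(step = 0.025) {
  k <- round(1 / step)
  if (abs(k * step - 1) > 1e-9) {
    stop("1/step must be an integer", call. = FALSE)
  }
  g <- tidyr::expand_grid(i = 0:k, j = 0:k)
  g <- dplyr::filter(g, .data$i + .data$j <= k)
  tibble::tibble(phi_oxy = 1 - (g$i + g$j) / k,
                 phi_deoxy = g$i / k,
                 phi_met = g$j / k)
}

#' Forward model: VSECS spectrum for a given composition
#'
#' Composes the complex-RI superposition, the Lorenz-Mie engine and the
#' PSD ensemble average into the volume-specific extinction cross
#' section that a measurement of this suspension would yield.
#' Deterministic: identical inputs give identical output.
#'
#' @param fractions an [hb_fractions()] row.
#' @param psd an `hb_psd`.
#' @param composition_base a [particle_composition()] supplying the
#'   intra-particle concentrations (fractions therein are ignored).
#' @param optics named list of [species_optics()].
#' @param wavelength_nm evaluation grid (nm).
#' @param d_step diameter quadrature step (nm).
#' @return `hb_spectrum` of kind `vsecs`.
#' @export
forward_vsecs <- function(fractions, psd,
                          composition_base = particle_composition(),
                          optics = hb_default_optics(),
                          wavelength_nm = seq(300, 800, by = 5),
                          d_step = 10) {
  comp <- particle_composition(composition_base$beta_hb,
                               composition_base$beta_glhsa, fractions)
  ri <- particle_complex_ri(comp, optics, wavelength_nm)
  ensemble_vsecs(psd, ri, n_medium = NULL, d_step = d_step)
}

#' Precompute forward VSECS spectra on a candidate set
#'
#' Evaluates the forward model once per candidate composition; the
#' resulting matrix can be passed to [fit_fractions()] as `model_cache`
#' so that many measured spectra (e.g. Monte-Carlo replicates) are
#' fitted against the same model grid without recomputation.
#'
#' @param candidates tibble with columns `phi_oxy`, `phi_deoxy`,
#'   `phi_met` (e.g. [simplex_grid()]).
#' @inheritParams forward_vsecs
#' @return list of class `hb_model_cache` with elements `candidates`,
#'   `wavelength_nm`, `z` (matrix, wavelengths x candidates) and the
#'   forward-model settings.
#' @export
vsecs_model_grid <- function(candidates, psd,
                             composition_base = particle_composition(),
                             optics = hb_default_optics(),
                             wavelength_nm = seq(300, 800, by = 5),
                             d_step = 10) {
  stopifnot(all(c("phi_oxy", "phi_deoxy", "phi_met") %in%
                  names(candidates)))
  zm <- vapply(seq_len(nrow(candidates)), function(i) {
    f <- hb_fractions(candidates$phi_oxy[i], candidates$phi_deoxy[i],
                      candidates$phi_met[i])
    forward_vsecs(f, psd, composition_base, optics, wavelength_nm,
                  d_step)$value
  }, numeric(length(wavelength_nm)))
  structure(list(candidates = tibble::as_tibble(candidates),
                 wavelength_nm = as.numeric(wavelength_nm),
                 z = matrix(zm, nrow = length(wavelength_nm)),
                 psd = psd, composition_base = composition_base,
                 d_step = d_step),
            class = "hb_model_cache")
}

#' Fit hemoglobin state fractions to a measured VSECS spectrum
#'
#' Inverts a measured volume-specific extinction spectrum to the mass
#' fractions of oxyHb, deoxyHb and metHb by least squares against the
#' forward model, with an optional free multiplicative scale that
#' absorbs the systematic offset between measured and simulated spectra
#' (particle loss, agglomeration, trapped volume in the PPV).
#'
#' Grid stage: the objective \eqn{\sum_\lambda (s Z_{model} - Z_{meas})^2}
#' is evaluated on a regular simplex grid, with the per-candidate optimal
#' scale in closed form when `allow_scale` is on.  Optimize stage
#' (default): a Nelder-Mead refinement in (phi_deoxy, phi_met), started
#' from the grid optimum, with the simplex constraint enforced by
#' penalty.  The standard uncertainty of the metHb fraction is estimated
#' from the curvature of the one-dimensional metHb profile of the grid
#' objective.
#'
#' @param z_meas `hb_spectrum` of kind `vsecs` (the measurement).
#' @param psd an `hb_psd`.
#' @param composition_base a [particle_composition()]; the intra-particle
#'   concentrations are held fixed during the fit.
#' @param optics named list of [species_optics()].
#' @param allow_scale logical; fit the free multiplicative scale
#'   (default `TRUE`).
#' @param mode `"optimize"` (grid then local refinement, default) or
#'   `"grid"` (grid only).
#' @param grid_step simplex grid step (default 0.025).
#' @param d_step diameter quadrature step (nm).
#' @param model_cache optional [vsecs_model_grid()] result on the same
#'   wavelength grid; skips the forward evaluations of the grid stage.
#' @return object of class `hb_fit`: fractions, scale, rss,
#'   uncertainty_met, the metHb profile and the fitted spectrum.
#' @export
fit_fractions <- function(z_meas, psd,
                          composition_base = particle_composition(),
                          optics = hb_default_optics(),
                          allow_scale = TRUE,
                          mode = c("optimize", "grid"),
                          grid_step = 0.025, d_step = 10,
                          model_cache = NULL) {
  stopifnot(inherits(z_meas, "hb_spectrum"))
  if (spectrum_kind(z_meas) != "vsecs") {
    stop("`z_meas` must be a spectrum of kind vsecs", call. = FALSE)
  }
  mode <- match.arg(mode)
  lam <- z_meas$wavelength_nm
  if (is.null(model_cache)) {
    model_cache <- vsecs_model_grid(simplex_grid(grid_step), psd,
                                    composition_base, optics, lam, d_step)
  } else {
    stopifnot(inherits(model_cache, "hb_model_cache"))
    if (length(model_cache$wavelength_nm) != length(lam) ||
        any(abs(model_cache$wavelength_nm - lam) > 1e-9)) {
      stop("`model_cache` wavelength grid does not match `z_meas`",
           call. = FALSE)
    }
    psd <- model_cache$psd
    composition_base <- model_cache$composition_base
    d_step <- model_cache$d_step
  }
  z <- z_meas$value
  zm <- model_cache$z
  cand <- model_cache$candidates

  num <- as.numeric(crossprod(zm, z))         # per-candidate sum(zm*z)
  den <- colSums(zm^2)
  s_cand <- if (allow_scale) num / den else rep(1, ncol(zm))
  # clamp: the closed form can go epsilon-negative on exact matches
  rss_cand <- pmax(sum(z^2) - 2 * s_cand * num + s_cand^2 * den, 0)
  best <- which.min(rss_cand)

  frac <- c(cand$phi_deoxy[best], cand$phi_met[best])
  scale <- s_cand[best]
  rss <- rss_cand[best]
  convergence <- 0L

  objective <- function(theta) {
    pd <- theta[1]; pm <- theta[2]
    viol <- max(0, -pd) + max(0, -pm) + max(0, pd + pm - 1)
    pd <- min(max(pd, 0), 1); pm <- min(max(pm, 0), 1)
    if (pd + pm > 1) {
      tot <- pd + pm; pd <- pd / tot; pm <- pm / tot
    }
    f <- hb_fractions(1 - pd - pm, pd, pm)
    zf <- forward_vsecs(f, psd, composition_base, optics, lam,
                        d_step)$value
    s <- if (allow_scale) sum(zf * z) / sum(zf^2) else 1
    sum((s * zf - z)^2) * (1 + 1e3 * viol) + 1e6 * viol^2
  }

  if (mode == "optimize") {
    opt <- stats::optim(frac, objective, method = "Nelder-Mead",
                        control = list(maxit = 200, reltol = 1e-10))
    if (opt$value <= rss) {
      frac <- pmin(pmax(opt$par, 0), 1)
      if (sum(frac) > 1) frac <- frac / sum(frac)
      rss <- opt$value
      convergence <- opt$convergence
    }
  }
  fractions <- hb_fractions(1 - sum(frac), frac[1], frac[2])
  z_fit <- forward_vsecs(fractions, psd, composition_base, optics, lam,
                         d_step)$value
  scale <- if (allow_scale) sum(z_fit * z) / sum(z_fit^2) else 1
  rss <- sum((scale * z_fit - z)^2)

  # metHb profile of the grid objective and its local curvature
  prof <- tibble::tibble(phi_met = cand$phi_met, rss = rss_cand)
  prof <- dplyr::summarise(dplyr::group_by(prof, .data$phi_met),
                           rss = min(.data$rss), .groups = "drop")
  prof <- dplyr::arrange(prof, .data$phi_met)
  u_met <- profile_uncertainty(prof, length(z))
  ill_posed <- is.na(u_met)

  structure(list(fractions = fractions, scale = scale, rss = rss,
                 uncertainty_met = u_met, ill_posed = ill_posed,
                 profile = prof, allow_scale = allow_scale, mode = mode,
                 convergence = convergence,
                 n_wavelengths = length(z),
                 z_meas = z_meas,
                 fitted = spectrum(lam, scale * z_fit, "vsecs")),
            class = "hb_fit")
}

# standard uncertainty of phi_met from the quadratic curvature of the
# grid profile RSS around its minimum: Var ~ 2*sigma^2 / d2RSS
profile_uncertainty <- function(prof, n_obs) {
  i0 <- which.min(prof$rss)
  if (i0 <= 1L || i0 >= nrow(prof)) return(NA_real_)
  h1 <- prof$phi_met[i0] - prof$phi_met[i0 - 1]
  h2 <- prof$phi_met[i0 + 1] - prof$phi_met[i0]
  curv <- 2 * (h1 * prof$rss[i0 + 1] + h2 * prof$rss[i0 - 1] -
                 (h1 + h2) * prof$rss[i0]) / (h1 * h2 * (h1 + h2))
  if (!is.finite(curv) || curv <= 0) return(NA_real_)
  dof <- max(n_obs - 3, 1)
  sigma2 <- prof$rss[i0] / dof
  sqrt(2 * sigma2 / curv)
}

#' @export
print.hb_fit <- function(x, ...) {
  f <- x$fractions
  cat("Hemoglobin composition fit\n")
  cat(sprintf("  phi_oxy   %.4f\n  phi_deoxy %.4f\n  phi_met   %.4f",
              f$phi_oxy, f$phi_deoxy, f$phi_met))
  if (!is.na(x$uncertainty_met)) {
    cat(sprintf("  (u = %.3f)", x$uncertainty_met))
  }
  cat(sprintf("\n  scale %.4f, rss %.4g over %d wavelengths\n",
              x$scale, x$rss, x$n_wavelengths))
  if (x$ill_posed) cat("  note: flat objective, uncertainty not resolved\n")
  invisible(x)
}
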