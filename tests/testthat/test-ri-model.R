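test_that("gamma_from_epsilon implements the extinction-to-increment link", {
  eps <- spectrum(574, 6945, "molar_extinction")
  g <- gamma_from_epsilon(eps, 16114.5)
  expect_equal(g$value, 4.533e-3, tolerance = 1e-3)
  expect_identical(spectrum_kind(g), "ri_increment_imag")

  # zero extinction gives zero increment; doubling M halves gamma
  grid <- seq(300, 800, 10)
  z <- gamma_from_epsilon(spectrum(grid, rep(0, length(grid)),
                                   "molar_extinction"))
  expect_true(all(z$value == 0))
  e2 <- spectrum(grid, runif(length(grid), 0, 1e5), "molar_extinction")
  expect_equal(gamma_from_epsilon(e2, 2 * 16114.5)$value,
               gamma_from_epsilon(e2, 16114.5)$value / 2)

  expect_error(gamma_from_epsilon(eps, -1), "positive")
})

test_that("gamma/epsilon conversion round-trips to machine precision", {
  grid <- seq(300, 800, 5)
  set.seed(1)
  eps <- spectrum(grid, runif(length(grid), 0, 1.3e5), "molar_extinction")
  g <- gamma_from_epsilon(eps)
  back <- epsilon_from_gamma(g)
  expect_equal(back$value, eps$value, tolerance = 1e-12)
})

test_that("water refractive index shows handbook value and normal dispersion", {
  n589 <- water_ri(589)$value
  expect_lt(abs(n589 - 1.333), 0.002)
  grid <- seq(300, 800, 10)
  n <- water_ri(grid)
  expect_equal(nrow(n), length(grid))
  expect_true(all(diff(n$value) < 0))
  expect_error(water_ri(150), "200-1100")
})

test_that("Kramers-Kronig transform is idempotent and matches the Lorentz pair", {
  grid <- seq(120, 3000, by = 1)
  zero <- spectrum(grid, rep(0, length(grid)), "ri_increment_imag")
  aref <- spectrum(grid, rep(0.2, length(grid)), "ri_increment_real")

  out <- kk_real_increment(zero, zero, aref)
  expect_equal(out$value, rep(0.2, nrow(out)), tolerance = 1e-14)

  set.seed(5)
  for (i in 1:3) {
    lam0 <- runif(1, 350, 700)
    G <- runif(1, 0.05, 0.3)
    f <- runif(1, 0.5, 2)
    lp <- lorentz_pair(grid, lam0, G, f)
    gt <- spectrum(grid, pmax(lp$im, 0), "ri_increment_imag")
    got <- kk_real_increment(gt, zero, zero_alpha <- spectrum(
      grid, rep(0, length(grid)), "ri_increment_real"))
    want <- lorentz_pair(got$wavelength_nm, lam0, G, f)$re
    im <- lp$im
    above <- which(im > max(im) / 2)
    hw <- (grid[max(above)] - grid[min(above)]) / 2
    sel <- abs(got$wavelength_nm - lam0) >= 2 * hw
    expect_lt(max(abs(got$value - want)[sel] / abs(want[sel])), 1e-3)
  }
})

test_that("a narrow absorption band produces anomalous dispersion around it", {
  grid <- seq(150, 1000, 1)
  zero <- spectrum(grid, rep(0, length(grid)), "ri_increment_imag")
  aref <- spectrum(grid, rep(0.2, length(grid)), "ri_increment_real")
  band <- spectrum(grid, 0.02 * exp(-(grid - 430)^2 / (2 * 8^2)),
                   "ri_increment_imag")
  out <- kk_real_increment(band, zero, aref)
  d_above <- out$value[out$wavelength_nm == 460] - 0.2
  d_below <- out$value[out$wavelength_nm == 400] - 0.2
  expect_gt(d_above, 0)   # long-wavelength side elevated
  expect_lt(d_below, 0)   # short-wavelength side depressed
})

test_that("KK transform validates grids and padding", {
  g1 <- spectrum(seq(250, 850, 1), rep(0, 601), "ri_increment_imag")
  g2 <- spectrum(seq(250, 850, 2), rep(0, 301), "ri_increment_imag")
  a1 <- spectrum(seq(250, 850, 1), rep(0.2, 601), "ri_increment_real")
  expect_error(kk_real_increment(g1, g2, a1), "common wavelength grid")
  short <- spectrum(seq(290, 810, 1), rep(0, 521), "ri_increment_imag")
  ashort <- spectrum(seq(290, 810, 1), rep(0.2, 521), "ri_increment_real")
  expect_warning(kk_real_increment(short, short, ashort), "beyond")
  expect_error(kk_real_increment(short, short, ashort, strict_pad = TRUE),
               "beyond")
})

test_that("particle complex RI superposes species increments over water", {
  # pure-water limit
  ri0 <- particle_complex_ri(
    particle_composition(0, 0, hb_fractions(1, 0, 0)), test_optics,
    seq(300, 800, 25))
  expect_equal(ri0$n, water_ri(seq(300, 800, 25))$value, tolerance = 1e-14)
  expect_true(all(ri0$kappa == 0))

  # single-species limit: kappa proportional to the metHb increment
  ri_met <- particle_complex_ri(
    particle_composition(120, 0, hb_fractions(0, 0, 1)), test_optics,
    seq(300, 800, 25))
  gam_met <- spectrum_interp(test_optics$metHb$gamma, seq(300, 800, 25))
  expect_equal(ri_met$kappa, 0.120 * gam_met$value, tolerance = 1e-12)

  # reference batch at 488 nm: n ~ 1.390 (tol 0.01), kappa ~ 3.6e-4
  # within a factor of two on the synthetic increment tables
  ri <- particle_complex_ri(
    particle_composition(120, 130, hb_fractions(0.65, 0, 0.35)),
    test_optics, 488)
  expect_lt(abs(ri$n - 1.390), 0.01)
  expect_gt(ri$kappa, 3.6e-4 / 2)
  expect_lt(ri$kappa, 3.6e-4 * 2)
})

test_that("complex RI is affine in concentrations and convex in fractions", {
  wl <- seq(300, 800, 50)
  f <- hb_fractions(0.3, 0.3, 0.4)
  nw <- water_ri(wl)$value
  ri1 <- particle_complex_ri(particle_composition(60, 65, f), test_optics, wl)
  ri2 <- particle_complex_ri(particle_composition(120, 130, f), test_optics, wl)
  expect_equal(ri2$n - nw, 2 * (ri1$n - nw), tolerance = 1e-12)
  expect_equal(ri2$kappa, 2 * ri1$kappa, tolerance = 1e-12)

  f1 <- hb_fractions(1, 0, 0); f2 <- hb_fractions(0, 0.2, 0.8)
  t <- 0.3
  fb <- hb_fractions(t * 1 + (1 - t) * 0, (1 - t) * 0.2, (1 - t) * 0.8)
  kb <- particle_complex_ri(particle_composition(120, 0, fb),
                            test_optics, wl)$kappa
  k1 <- particle_complex_ri(particle_composition(120, 0, f1),
                            test_optics, wl)$kappa
  k2 <- particle_complex_ri(particle_composition(120, 0, f2),
                            test_optics, wl)$kappa
  expect_equal(kb, t * k1 + (1 - t) * k2, tolerance = 1e-12)
})

test_that("fraction and composition constructors reject invalid input", {
  expect_error(hb_fractions(0.6, 0.6, 0.1), "sum to 1")
  expect_error(hb_fractions(-0.1, 0.6, 0.5), "\\[0, 1\\]")
  expect_error(particle_composition(-1, 0), "non-negative")
  expect_error(particle_complex_ri(
    particle_composition(120, 130, hb_fractions(1, 0, 0)),
    test_optics[c("oxyHb", "GlHSA")], 500), "species tables")
})
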