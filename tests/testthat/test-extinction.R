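make_meas <- function(tvals, wl = seq(300, 800, length.out = length(tvals)),
                      phi = 1e-3, ppv = 0.1992, c0 = NULL, path = 10) {
  transmittance_measurement(spectrum(wl, tvals, "transmittance"),
                            path_length_mm = path, volume_fraction = phi,
                            ppv = ppv, stock_concentration = c0)
}

test_that("Beer-Lambert inversions reproduce hand-audited values", {
  # full transmission means zero extinction on both routes
  m1 <- make_meas(rep(1, 6), c0 = 1)
  expect_true(all(transmittance_to_cext(m1)$value == 0))
  expect_true(all(transmittance_to_vsecs(m1)$value == 0))

  # T = 1/e, l = 10 mm, C0 = 1 pL^-1, phi = 0.1 -> Cext = 1 um^2
  m2 <- make_meas(rep(exp(-1), 3), phi = 0.1, c0 = 1)
  expect_equal(transmittance_to_cext(m2)$value, rep(1, 3),
               tolerance = 1e-12)

  # T = 1/e, l = 10 mm, PPV = 0.1992, phi = 5e-4 -> Z = 1.004 um^-1
  m3 <- make_meas(rep(exp(-1), 3), phi = 5e-4, ppv = 0.1992)
  expect_equal(transmittance_to_vsecs(m3)$value,
               rep(1 / (1e4 * 0.1992 * 5e-4), 3), tolerance = 1e-12)
  expect_equal(transmittance_to_vsecs(m3)$value[1], 1.004,
               tolerance = 1e-3)

  # doubling phi halves the inferred cross section
  m4 <- make_meas(rep(0.5, 3), phi = 0.2, c0 = 1)
  expect_equal(transmittance_to_cext(m4)$value,
               transmittance_to_cext(m2 <- make_meas(rep(0.5, 3),
                                                     phi = 0.4,
                                                     c0 = 1))$value * 2)
})

test_that("per-particle and volume-specific routes agree when C0 = PPV/V", {
  vbar <- mean_volume(test_psd)           # um^3
  ppv <- 0.1992
  c0 <- ppv / vbar * 1e3                  # pL^-1
  m <- make_meas(seq(0.4, 0.9, length.out = 11), phi = 5e-4, ppv = ppv,
                 c0 = c0)
  z1 <- transmittance_to_vsecs(m)$value
  z2 <- transmittance_to_cext(m)$value / vbar
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("lower transmittance maps to higher extinction", {
  m <- make_meas(c(0.3, 0.5, 0.7, 0.9))
  z <- transmittance_to_vsecs(m)$value
  expect_true(all(diff(z) < 0))
})

test_that("measurement constructor and converters validate inputs", {
  s <- spectrum(c(300, 800), c(0.5, 0.9), "transmittance")
  expect_error(transmittance_measurement(s, volume_fraction = 2),
               "\\(0, 1\\)")
  expect_error(transmittance_measurement(s, path_length_mm = 0,
                                         volume_fraction = 0.1), "> 0")
  m <- transmittance_measurement(s, volume_fraction = 0.1)
  expect_error(transmittance_to_vsecs(m), "ppv")
  expect_error(transmittance_to_cext(m), "stock_concentration")
})

test_that("dilution selection takes the densest artefact-free member", {
  wl <- seq(300, 800, 10)
  ser <- make_dilution_series(hb_fractions(0.65, 0, 0.35), test_psd,
                              optics = test_optics, wavelength_nm = wl,
                              d_step = 20)
  sel <- select_dilution(ser)
  qc <- attr(sel, "qc")
  # members below 30% transmittance are rejected, the densest passing one wins
  expect_false(any(qc$pass[qc$t_min_window < 0.30]))
  expect_equal(sel$volume_fraction, max(qc$volume_fraction[qc$pass]))

  # a single compliant measurement is returned unchanged
  one <- select_dilution(ser[4])
  expect_equal(one$volume_fraction, ser[[4]]$volume_fraction)

  # an injected multiple-scattering artefact in an otherwise compliant
  # member breaks the log-shift consistency and the next dilution wins
  ser2 <- make_dilution_series(hb_fractions(0.65, 0, 0.35), test_psd,
                               optics = test_optics, wavelength_nm = wl,
                               d_step = 20, multiple_scattering = TRUE,
                               ms_threshold = 0.55, ms_strength = 0.4)
  sel2 <- select_dilution(ser2)
  expect_lt(sel2$volume_fraction, sel$volume_fraction)

  # nothing compliant (the two densest members) -> QC failure
  expect_error(select_dilution(ser[5:6]), "no dilution passes QC")
})

test_that("least-squares rescaling recovers known scale factors", {
  wl <- seq(300, 800, 10)
  z <- forward_vsecs(hb_fractions(0.65, 0, 0.35), test_psd,
                     optics = test_optics, wavelength_nm = wl,
                     d_step = 20)
  # identical input: scale 1; halved input: scale 2
  expect_equal(rescale_to_reference(z, z)$scale, 1, tolerance = 1e-12)
  half <- spectrum(wl, z$value / 2, "vsecs")
  rs <- rescale_to_reference(half, z)
  expect_equal(rs$scale, 2, tolerance = 1e-12)
  expect_equal(rs$spectrum$value, z$value, tolerance = 1e-12)

  # 1% multiplicative noise on a doubled reference: scale 2.00 +- 0.01
  set.seed(3)
  zr <- spectrum(wl, 2 * z$value * (1 + rnorm(length(wl), 0, 0.01)),
                 "vsecs")
  expect_equal(rescale_to_reference(z, zr)$scale, 2, tolerance = 5e-3)

  zero <- spectrum(wl, rep(0, length(wl)), "vsecs")
  expect_error(rescale_to_reference(zero, z), "identically zero")
})
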