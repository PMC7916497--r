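wl_fit <- seq(300, 800, 10)
comp_base <- particle_composition(120, 130)

test_that("forward model is deterministic and shows the band signatures", {
  z1 <- forward_vsecs(hb_fractions(0.65, 0, 0.35), test_psd, comp_base,
                      test_optics, wl_fit, d_step = 20)
  z2 <- forward_vsecs(hb_fractions(0.65, 0, 0.35), test_psd, comp_base,
                      test_optics, wl_fit, d_step = 20)
  expect_identical(z1$value, z2$value)   # bit-for-bit

  wl_soret <- seq(380, 470, 1)
  z_oxy <- forward_vsecs(hb_fractions(1, 0, 0), test_psd, comp_base,
                         test_optics, wl_soret, d_step = 20)
  z_met <- forward_vsecs(hb_fractions(0, 0, 1), test_psd, comp_base,
                         test_optics, wl_soret, d_step = 20)
  z_deo <- forward_vsecs(hb_fractions(0, 1, 0), test_psd, comp_base,
                         test_optics, wl_soret, d_step = 20)
  # Soret extinction maximum: metHb below oxyHb below deoxyHb
  expect_lt(wl_soret[which.max(z_met$value)],
            wl_soret[which.max(z_oxy$value)])
  expect_lt(wl_soret[which.max(z_oxy$value)],
            wl_soret[which.max(z_deo$value)])
})

test_that("simplex grid enumerates valid compositions", {
  g <- simplex_grid(0.1)
  expect_equal(nrow(g), 66)
  expect_true(all(abs(g$phi_oxy + g$phi_deoxy + g$phi_met - 1) < 1e-12))
  expect_true(all(g$phi_oxy >= 0 & g$phi_deoxy >= 0 & g$phi_met >= 0))
  expect_error(simplex_grid(0.03), "integer")
})

test_that("noiseless round trip recovers fractions and scale", {
  cache <- vsecs_model_grid(simplex_grid(0.05), test_psd, comp_base,
                            test_optics, wl_fit, d_step = 20)
  f0 <- hb_fractions(0.65, 0, 0.35)
  z0 <- forward_vsecs(f0, test_psd, comp_base, test_optics, wl_fit,
                      d_step = 20)
  z_meas <- spectrum(wl_fit, 0.85 * z0$value, "vsecs")
  fit <- fit_fractions(z_meas, test_psd, optics = test_optics,
                       model_cache = cache)
  expect_lt(abs(fit$fractions$phi_met - 0.35), 0.01)
  expect_lt(abs(fit$fractions$phi_oxy - 0.65), 0.01)
  expect_lt(abs(fit$scale - 0.85), 0.01)

  # pure-metHb vertex
  z_met <- forward_vsecs(hb_fractions(0, 0, 1), test_psd, comp_base,
                         test_optics, wl_fit, d_step = 20)
  fit_met <- fit_fractions(z_met, test_psd, optics = test_optics,
                           model_cache = cache)
  expect_gte(fit_met$fractions$phi_met, 0.975)
})

test_that("grid objective has its minimum at on-grid generating points", {
  cache <- vsecs_model_grid(simplex_grid(0.05), test_psd, comp_base,
                            test_optics, wl_fit, d_step = 20)
  for (f in list(c(0.6, 0.1, 0.3), c(0.2, 0.45, 0.35), c(0, 0.5, 0.5))) {
    z <- forward_vsecs(hb_fractions(f[1], f[2], f[3]), test_psd,
                       comp_base, test_optics, wl_fit, d_step = 20)
    fit <- fit_fractions(z, test_psd, optics = test_optics,
                         mode = "grid", model_cache = cache)
    expect_equal(fit$fractions$phi_oxy, f[1], tolerance = 1e-9)
    expect_equal(fit$fractions$phi_met, f[3], tolerance = 1e-9)
  }
})

test_that("a rescaled measurement changes only the fitted scale", {
  cache <- vsecs_model_grid(simplex_grid(0.05), test_psd, comp_base,
                            test_optics, wl_fit, d_step = 20)
  z0 <- forward_vsecs(hb_fractions(0.5, 0.2, 0.3), test_psd, comp_base,
                      test_optics, wl_fit, d_step = 20)
  fit1 <- fit_fractions(z0, test_psd, optics = test_optics,
                        mode = "grid", model_cache = cache)
  z3 <- spectrum(wl_fit, 3 * z0$value, "vsecs")
  fit3 <- fit_fractions(z3, test_psd, optics = test_optics,
                        mode = "grid", model_cache = cache)
  expect_equal(fit3$fractions$phi_met, fit1$fractions$phi_met)
  expect_equal(fit3$fractions$phi_oxy, fit1$fractions$phi_oxy)
  expect_equal(fit3$scale, 3 * fit1$scale, tolerance = 1e-9)
})

test_that("fit object supports tidy, glance and autoplot", {
  cache <- vsecs_model_grid(simplex_grid(0.1), test_psd, comp_base,
                            test_optics, wl_fit, d_step = 20)
  z0 <- forward_vsecs(hb_fractions(0.6, 0.1, 0.3), test_psd, comp_base,
                      test_optics, wl_fit, d_step = 20)
  fit <- fit_fractions(z0, test_psd, optics = test_optics,
                       mode = "grid", model_cache = cache)
  td <- tidy(fit)
  expect_equal(td$term, c("phi_oxy", "phi_deoxy", "phi_met"))
  expect_equal(sum(td$estimate), 1, tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$nobs, length(wl_fit))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(z0), "ggplot")
  expect_output(print(fit), "phi_met")
})

test_that("fit validates input kind and cache compatibility", {
  z0 <- forward_vsecs(hb_fractions(0.6, 0.1, 0.3), test_psd, comp_base,
                      test_optics, wl_fit, d_step = 20)
  not_z <- spectrum(wl_fit, rep(0.5, length(wl_fit)), "transmittance")
  expect_error(fit_fractions(not_z, test_psd), "vsecs")
  cache <- vsecs_model_grid(simplex_grid(0.1), test_psd, comp_base,
                            test_optics, seq(300, 800, 20), d_step = 20)
  expect_error(fit_fractions(z0, test_psd, optics = test_optics,
                             model_cache = cache), "does not match")
})
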