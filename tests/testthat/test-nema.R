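test_that("Gaussian PSF fit recovers the closed-form widths", {
  p <- seq(-6, 6, by = 0.25)
  prof <- data.frame(position = p, value = 3 * exp(-p^2 / 2))
  fit <- fit_psf(prof)
  expect_equal(fit$fwhm, 2 * sqrt(2 * log(2)), tolerance = 1e-6)
  expect_equal(fit$fwhm, 2.3548, tolerance = 1e-4)
  expect_equal(fit$fwtm, 4.2919, tolerance = 1e-4)
  expect_equal(fit$fwtm / fit$fwhm, 1.8226, tolerance = 1e-4)
  expect_equal(fit$center, 0, tolerance = 1e-8)
})

test_that("PSF fit is robust to noise and equivariant under scaling", {
  p <- seq(-6, 6, by = 0.25)
  clean <- exp(-p^2 / 2)
  fwhms <- planarpet:::with_seed(77, vapply(1:50, function(i) {
    prof <- data.frame(position = p,
                       value = clean + rnorm(length(p), 0, 0.05))
    fit_psf(prof)$fwhm
  }, numeric(1)))
  expect_equal(mean(fwhms), 2.3548, tolerance = 0.02 * 2.3548)
  # scaling positions by k scales fwhm and fwtm by k
  k <- 3.7
  f1 <- fit_psf(data.frame(position = p, value = clean))
  f2 <- fit_psf(data.frame(position = k * p, value = clean))
  expect_equal(f2$fwhm, k * f1$fwhm, tolerance = 1e-6)
  expect_equal(f2$fwtm, k * f1$fwtm, tolerance = 1e-6)
  expect_error(fit_psf(data.frame(position = 1:3, value = c(0, 1, 0))),
               class = "planarpet_domain_error")
})

test_that("sensitivity records implement the rate-normalization identities", {
  mk <- function(n, dur, pos) {
    ev <- perp_events(n)
    ev$t <- seq(0, dur - 1e-9, length.out = n)
    make_set(ev, duration = dur, meta = list(position_mm = pos))
  }
  # R - R_B = 2876.8 cps over A_cal = 89.9 kBq -> S = 32.0 cps/kBq -> 3.5 %
  acq <- mk(28768, 10, 0)
  prof <- sensitivity_profile(list(acq), NULL, a_cal = 89.9)
  expect_equal(prof$records$s_cps_per_kbq, 2876.8 / 89.9, tolerance = 1e-12)
  expect_equal(prof$records$s_cps_per_kbq, 32.0, tolerance = 1e-3)
  expect_equal(prof$records$s_abs_percent,
               (2876.8 / 89.9) / 1000 / 0.9060 * 100, tolerance = 1e-9)
  expect_equal(signif(prof$records$s_abs_percent, 2), 3.5)
  # R_i = R_B_i gives exactly zero
  bg <- mk(500, 10, NA)
  prof0 <- sensitivity_profile(list(mk(500, 10, 4)), bg, a_cal = 89.9)
  expect_identical(prof0$records$s_abs_percent, 0)
  # Eq. (2) is a strict proportionality with constant 100 / (1000 * BR)
  many <- lapply(c(100, 2000, 28768), mk, dur = 10, pos = 0)
  prof2 <- sensitivity_profile(many, NULL, a_cal = 89.9)
  expect_equal(prof2$records$s_abs_percent,
               prof2$records$s_cps_per_kbq * 100 / (1000 * 0.9060),
               tolerance = 1e-12)
  expect_lte(prof2$average_abs, prof2$peak_abs)
  expect_error(sensitivity_profile(many, NULL, a_cal = 0),
               class = "planarpet_domain_error")
})

test_that("NECR identity reproduces the printed peak rates", {
  # peak trues / scatter / randoms at the 110 mm allowance
  expect_equal(necr_rate(32.5, 20.9, 5.76), 17.855, tolerance = 1e-3)
  expect_equal(necr_rate(32.5, 20.9, 5.76), 17.8, tolerance = 0.01 * 17.8)
  expect_identical(necr_rate(0, 0, 0), 0)
  expect_true(all(necr_rate(c(1, 5), c(0.2, 1), c(0, 0.5)) <= c(1, 5)))
  expect_equal(necr_rate(4, 0, 0), 4)
})

test_that("efficiency at peak reproduces the published system comparisons", {
  own <- efficiency_at_peak(necr_peak_kcps = 17.8, concentration_at_peak = 10.5,
                            volume_ml = 300)
  expect_equal(own$activity_at_peak_mbq, 3.15, tolerance = 1e-12)
  expect_equal(own$efficiency, 5650.79, tolerance = 1e-4)
  expect_equal(signif(own$efficiency, 3), 5650)
  total_body <- efficiency_at_peak(necr_peak_kcps = 1440,
                                   concentration_at_peak = 16.8,
                                   volume_ml = 22600)
  expect_equal(total_body$efficiency, 3790, tolerance = 0.002 * 3790)
  ring_pem <- efficiency_at_peak(necr_peak_kcps = 34.0,
                                 concentration_at_peak = 31.2,
                                 volume_ml = 866)
  expect_equal(ring_pem$efficiency, 1260, tolerance = 0.002 * 1260)
  zero <- efficiency_at_peak(necr_peak_kcps = 0, concentration_at_peak = 10,
                             volume_ml = 300)
  expect_identical(zero$efficiency, 0)
  expect_error(efficiency_at_peak(necr_peak_kcps = 1, concentration_at_peak = 0,
                                  volume_ml = 300),
               class = "planarpet_domain_error")
})

test_that("SUV concentrations follow the injected-dose normalization", {
  expect_identical(suv_concentration(0, 370), 0)
  expect_equal(suv_concentration(1, 370), 370000 / 77300, tolerance = 1e-12)
  expect_equal(suv_concentration(1, 370), 4.79, tolerance = 1e-3)
  expect_equal(suv_concentration(7, 37), 7 * 37000 / 77300, tolerance = 1e-12)
  expect_equal(suv_concentration(7, 37), 3.35, tolerance = 1e-3)
  expect_error(suv_concentration(1, 370, body_mass_kg = 0),
               class = "planarpet_domain_error")
})

test_that("scatter-free frames give zero scatter fraction and NECR = T", {
  clean <- nu4_scatter_phantom(activity_kbq = 400)
  clean$medium <- NULL   # line source without the attenuating body
  frames <- lapply(1:4, function(i)
    simulate_acquisition(clean, geom60, resp_cal, duration = 20,
                         seed = 60 + i, include_randoms = FALSE,
                         max_decays = 4e5))
  expect_identical(truth_scatter_fraction(frames), 0)
  # analyzed under the count-rate protocol's angle-allowance filter
  frames <- lapply(frames, apply_angle_allowance, allowance = 110)
  cs <- suppressWarnings(countrate_decompose(frames))
  # the band estimator has a small floor (~1-2 %) from oblique trues emitted
  # off the midplane reaching the band edges; far below any measured SF
  expect_lt(cs$scatter_fraction, 0.02)
  expect_equal(cs$points$necr, cs$points$trues, tolerance = 0.02)
  expect_true(all(cs$points$necr <= cs$points$trues + 1e-9))
})
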