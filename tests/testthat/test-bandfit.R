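test_that("pseudo-Voigt profile has the defining height and half-width behaviour", {
  for (eta in c(0, 0.25, 0.5, 0.75, 1)) {
    expect_equal(pseudo_voigt(898, 898, 8, 1, eta), 1)
    expect_equal(pseudo_voigt(898 + 4, 898, 8, 1, eta), 0.5)
    expect_equal(pseudo_voigt(898 - 4, 898, 8, 1, eta), 0.5)
  }
  # Lorentzian tails exceed Gaussian tails
  expect_gt(pseudo_voigt(930, 898, 8, 1, 1), pseudo_voigt(930, 898, 8, 1, 0))
})

test_that("analytic band area matches the closed forms and full-line quadrature", {
  expect_equal(band_area(fwhm = 10, height = 1, eta = 1), 15.70796,
               tolerance = 1e-6)
  expect_equal(band_area(fwhm = 10, height = 1, eta = 0), 10.64467,
               tolerance = 1e-6)
  expect_equal(band_area(fwhm = 10, height = 1, eta = 0.5), 13.17632,
               tolerance = 1e-6)
  for (eta in c(0, 0.25, 0.5, 0.75, 1)) {
    # integrate in the band-centred frame so the doubly-infinite
    # transformation sees the peak at the origin
    quad <- integrate(function(d) pseudo_voigt(898 + d, 898, 10, 0.7, eta),
                      -Inf, Inf, rel.tol = 1e-10)$value
    ana <- band_area(fwhm = 10, height = 0.7, eta = eta)
    expect_lt(abs(ana - quad) / quad, 1e-6)
  }
  # the band constructor stores the analytic area
  b <- band(898, 8, 0.9, 0.3)
  expect_lt(abs(b$area - band_area(fwhm = 8, height = 0.9, eta = 0.3)) /
              b$area, 1e-9)
})

test_that("a noiseless single band is recovered from an offset seed", {
  nu <- seq(850, 950, by = 0.5)
  s <- raman_spectrum(nu, pseudo_voigt(nu, 898, 8, 1, 0.5))
  fit <- fit_bands(s, c(850, 950), 898 - 3)
  expect_true(fit$converged)
  expect_lt(abs(fit$bands$center[1] - 898), 0.05)
  truth <- band_area(fwhm = 8, height = 1, eta = 0.5)
  expect_lt(abs(fit$bands$area[1] - truth) / truth, 0.005)
})

test_that("two overlapping noisy bands at 887/898 are resolved", {
  nu <- seq(850, 950, by = 0.5)
  y <- pseudo_voigt(nu, 887, 8, 0.5, 0.5) + pseudo_voigt(nu, 898, 8, 1, 0.5)
  set.seed(5)
  s <- raman_spectrum(nu, y + rnorm(length(nu), 0, 0.005))
  fit <- fit_bands(s, c(850, 950), c(887, 898))
  expect_true(fit$converged)
  expect_equal(nrow(fit$bands), 2)
  expect_lt(abs(fit$bands$center[1] - 887), 0.5)
  expect_lt(abs(fit$bands$center[2] - 898), 0.5)
  a887 <- band_area(fwhm = 8, height = 0.5, eta = 0.5)
  a898 <- band_area(fwhm = 8, height = 1, eta = 0.5)
  expect_lt(abs(fit$bands$area[1] - a887) / a887, 0.05)
  expect_lt(abs(fit$bands$area[2] - a898) / a898, 0.05)
})

test_that("a zero spectrum fits to zero height and converges", {
  nu <- seq(850, 950, by = 0.5)
  s <- raman_spectrum(nu, rep(0, length(nu)))
  fit <- fit_bands(s, c(850, 950), 898)
  expect_true(fit$converged)
  expect_lt(fit$bands$height[1], 1e-6)
})

test_that("reported residual RMS reconstructs data minus model", {
  s <- make_known_spectrum(noise_sigma = 0.004, seed = 9)
  fit <- fit_bands(s, c(850, 950), c(887, 898))
  manual <- sqrt(mean((fit$data$intensity -
                         predict(fit, fit$data$wavenumber))^2))
  expect_lt(abs(fit$residual_rms - manual), 1e-12)
  expect_equal(residuals(fit), fit$data$intensity - fitted(fit))
})

test_that("eta treatment is configurable: shared, free, fixed", {
  nu <- seq(850, 950, by = 0.5)
  y <- pseudo_voigt(nu, 880, 8, 1, 0.9) + pseudo_voigt(nu, 910, 8, 0.8, 0.1)
  s <- raman_spectrum(nu, y)
  free <- fit_bands(s, c(850, 950), c(880, 910), eta = "free")
  expect_lt(abs(free$bands$eta[1] - 0.9), 0.05)
  expect_lt(abs(free$bands$eta[2] - 0.1), 0.05)
  fixed <- fit_bands(s, c(850, 950), c(880, 910), eta = 0.25)
  expect_true(all(fixed$bands$eta == 0.25))
  shared <- fit_bands(s, c(850, 950), c(880, 910), eta = "shared")
  expect_equal(shared$bands$eta[1], shared$bands$eta[2])
})

test_that("seed validation and optimizer failure contracts hold", {
  nu <- seq(850, 950, by = 0.5)
  s <- raman_spectrum(nu, pseudo_voigt(nu, 898, 8, 1, 0.5))
  expect_error(fit_bands(s, c(850, 950), 1000), "inside the fit window")
  expect_error(fit_bands(s, c(2000, 2100), 2050), "data points")
  expect_error(fit_bands(s, c(850, 950), list()), "at least one seed")
})

test_that("areal_intensity_at picks the nearest band, breaks ties by area, and names missing targets", {
  fit <- fake_band_fit(c(885.5, 898.2), c(1.2, 2.5))
  expect_equal(areal_intensity_at(fit, 887, tol = 5), 1.2)
  expect_error(areal_intensity_at(fit, 1204, tol = 5), "1204")
  tie <- fake_band_fit(c(885, 889), c(0.7, 1.9))
  expect_equal(areal_intensity_at(tie, 887, tol = 5), 1.9)
})

test_that("degenerate collapsing bands are merged with areas summed", {
  bands <- data.frame(center = c(898.0, 898.3, 920), fwhm = c(8, 8, 8),
                      height = c(1, 1, 1), eta = 0.5,
                      area = c(2, 1, 3))
  merged <- steviaQC:::merge_degenerate_bands(bands)
  expect_equal(nrow(merged), 2)
  expect_equal(sort(merged$area), c(3, 3))
  expect_equal(merged$center[1], (2 * 898.0 + 1 * 898.3) / 3)
})
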