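# Shared fixtures, built in code.

# The reference calibration (12 noiseless library spectra through the full
# pipeline) is expensive enough to build once per test run.
.test_cache <- new.env()
ref_calibration <- function() {
  if (is.null(.test_cache$cal)) .test_cache$cal <- calibrate_reference()
  .test_cache$cal
}

# Published product ring estimates as a named list of ring_estimate objects.
product_estimates <- function() {
  tab <- stevia_products()
  out <- lapply(seq_len(nrow(tab)), function(i) {
    ring_estimate(tab$rings_c19[i], tab$total_rings_1[i], tab$total_rings_2[i])
  })
  stats::setNames(out, tab$product)
}

# A minimal spectrum covering all three analysis windows, with fully known
# injected band areas (areas in a.u.; eta 0.5, fwhm 8 except carbonyl 10).
make_known_spectrum <- function(a887 = 2.0, a898 = 1.0, a1192 = 0.6,
                                a1215 = 0.9, a1204 = 1.0, co_center = 1719,
                                a_co = 0.5, noise_sigma = 0, seed = 1,
                                extra_center = NULL, extra_area = 0) {
  bands <- data.frame(
    center = c(740, 887, 898, 1004, 1030, 1075, 1192, 1204, 1215, 1670, co_center),
    area = c(0.4, a887, a898, 0.5, 0.7, 0.6, a1192, a1204, a1215, 0.6, a_co),
    fwhm = c(rep(8, 10), 10), eta = 0.5)
  if (!is.null(extra_center)) {
    bands <- rbind(bands, data.frame(center = extra_center, area = extra_area,
                                     fwhm = 8, eta = 0.5))
  }
  bands$height <- bands$area / vapply(seq_len(nrow(bands)), function(i) {
    band_area(fwhm = bands$fwhm[i], height = 1, eta = bands$eta[i])
  }, numeric(1))
  nu <- seq(150, 2150, by = 0.5)
  y <- numeric(length(nu))
  for (i in seq_len(nrow(bands))) {
    y <- y + pseudo_voigt(nu, bands$center[i], bands$fwhm[i],
                          bands$height[i], bands$eta[i])
  }
  if (noise_sigma > 0) {
    set.seed(seed)
    y <- y + rnorm(length(nu), 0, noise_sigma)
  }
  raman_spectrum(nu, y)
}

# Minimal hand-built band_fit for selection/composition logic tests.
fake_band_fit <- function(centers, areas, window = range(centers) + c(-20, 20)) {
  bands <- data.frame(center = centers, fwhm = 8, height = areas / 8,
                      eta = 0.5, area = areas)
  nu <- seq(window[1], window[2], by = 0.5)
  structure(list(window = window, bands = bands[order(bands$center), ],
                 residual_rms = 0, converged = TRUE,
                 data = data.frame(wavenumber = nu,
                                   intensity = numeric(length(nu))),
                 seeds = data.frame(center = centers, fwhm = 8,
                                    height = areas / 8, eta = 0.5),
                 message = "synthetic"),
            class = "band_fit")
}
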