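test_that("compute_parameters recovers injected areal ratios and the carbonyl center", {
  # injected areas: 2.0 at 887 vs 1.0 at 898; 0.6/0.9 at 1192/1215 vs 1.0 at 1204
  s <- preprocess(make_known_spectrum(a887 = 2.0, a898 = 1.0, a1192 = 0.6,
                                      a1215 = 0.9, a1204 = 1.0,
                                      co_center = 1719))
  p <- compute_parameters(s)
  expect_s3_class(p, "raman_parameters")
  expect_equal(p$r1, 2.0, tolerance = 0.05 / 2.0)
  expect_equal(p$r2, 1.5, tolerance = 0.05 / 1.5)
  expect_equal(p$nu_co, 1719, tolerance = 0.3 / 1719)

  # a pure 0-ring-class compound lands on the 1706 anchor
  s0 <- preprocess(synth_spectrum("Rebaudioside B", noise_sigma = 0))
  p0 <- compute_parameters(s0)
  expect_lt(abs(p0$nu_co - 1706), 0.3)

  short <- raman_spectrum(seq(850, 950, 0.5), rep(1, 201))
  expect_error(compute_parameters(short), "does not cover")
})

test_that("ring estimates follow the defining arithmetic of the published product table", {
  tab <- stevia_products()
  printed <- c("Morita 1" = 1.88, "Morita 2" = 3.02, "China 1" = 3.03,
               "China 2" = 2.63, "Fermented" = 2.77)
  for (i in seq_len(nrow(tab))) {
    est <- ring_estimate(tab$rings_c19[i], tab$total_rings_1[i],
                         tab$total_rings_2[i])
    expect_equal(est$n13, est$ntot_r1 - est$n19)
    expect_equal(round(est$ratio_c13_c19, 2),
                 unname(printed[tab$product[i]]))
  }
  # Morita 1 worked example
  est <- ring_estimate(1.15, 3.31)
  expect_equal(round(est$n13, 2), 2.16)
  expect_equal(round(est$ratio_c13_c19, 2), 1.88)
  # near-zero C19 rings leave the ratio undefined
  est0 <- ring_estimate(0.01, 2.5)
  expect_true(is.na(est0$ratio_c13_c19))
  expect_true("ratio_undefined" %in% est0$flags)
})

test_that("the full inversion chain recovers a pure compound's ring structure", {
  cal <- ref_calibration()
  p <- compute_parameters(preprocess(synth_spectrum("Rebaudioside M",
                                                    noise_sigma = 0)))
  est <- estimate_rings(p, cal$nu_co, cal$r1, cal$r2)
  expect_lt(abs(est$n19 - 3), 0.25)
  expect_lt(abs(est$ntot_r1 - 6), 0.25)
  expect_lt(abs(est$ntot_r2 - 6), 0.25)
  expect_lt(abs(est$ntot_r1 - est$ntot_r2), 0.1)
  expect_equal(est$n13, est$ntot_r1 - est$n19)
})

test_that("carbonyl composition fractions are area proportions that sum to one", {
  single <- fake_band_fit(1719, 2.4, window = c(1640, 1780))
  comp1 <- carbonyl_composition(single)
  expect_equal(comp1$fraction, 1.0)
  three <- fake_band_fit(c(1706, 1719, 1738), c(1, 2, 7),
                         window = c(1640, 1780))
  comp3 <- carbonyl_composition(three)
  expect_equal(sum(comp3$fraction), 1, tolerance = 1e-9)
  expect_equal(comp3$fraction, c(0.1, 0.2, 0.7))
  expect_equal(comp3$class, c("0-ring", "1-ring", "linked"))
  # bands outside the carbonyl window are ignored
  with1670 <- fake_band_fit(c(1670, 1719), c(5, 2.4), window = c(1640, 1780))
  expect_equal(carbonyl_composition(with1670)$fraction, 1.0)
})

test_that("an injected low-wavenumber carbonyl fraction is recovered within two points", {
  # 18.1% of the carbonyl area in the 0-ring class, the rest 1-ring
  b <- blend_spec(c("Rebaudioside B" = 0.181, "Stevioside" = 0.819),
                  noise_sigma = 0)
  s <- preprocess(synth_spectrum(b))
  p <- compute_parameters(s)
  comp <- carbonyl_composition(p$window_fits$carbonyl)
  expect_equal(sum(comp$fraction), 1, tolerance = 1e-9)
  low <- sum(comp$fraction[comp$center < 1710])
  expect_lt(abs(low - 0.181), 0.02)
})

test_that("the extraneous-band flag fires on an 869 injection and stays quiet otherwise", {
  cal <- ref_calibration()
  clean <- synth_spectrum("Rebaudioside A", noise_sigma = 0.005, seed = 21)
  pre <- preprocess(clean)
  p <- compute_parameters(pre)
  res_clean <- detect_extraneous_band(pre, p$window_fits$glucose)
  expect_false(res_clean$flag)

  spiked <- synth_spectrum(blend_spec(c("Rebaudioside A" = 1),
                                      noise_sigma = 0, seed = 21,
                                      extraneous_869_area = 0.085))
  pre2 <- preprocess(spiked)
  p2 <- compute_parameters(pre2)
  res_sp <- detect_extraneous_band(pre2, p2$window_fits$glucose)
  expect_true(res_sp$flag)
  expect_lt(abs(res_sp$center - 869), 1)
  expect_gt(res_sp$relative_area, 0.01)
  expect_match(res_sp$note, "tentative")

  # extra intensity at an assigned center (887) is claimed by the assignment
  boosted <- preprocess(make_known_spectrum(a887 = 2.6))
  fit <- fit_bands(boosted, c(850, 950), c(887, 898),
                   center_tol = c(4.95, 4.95))
  res_887 <- detect_extraneous_band(boosted, fit)
  expect_false(res_887$flag)
})

test_that("taste labels reproduce the published comparative grading", {
  labels <- classify_taste(product_estimates())
  row <- function(p) labels[labels$product == p, ]
  m1 <- row("Morita 1")
  expect_equal(m1$sweetness, "highest")
  expect_equal(m1$sweet_perception, "fastest")
  expect_equal(m1$bitter_perception, "shortest")
  c1 <- row("China 1")
  expect_equal(c1$sweetness, "intermediate")
  expect_equal(c1$sweet_perception, "slow")
  expect_equal(c1$bitter_perception, "long")
  for (p in c("Morita 2", "China 2", "Fermented")) {
    expect_equal(row(p)$sweetness, "lowest")
    expect_equal(row(p)$sweet_perception, "slowest")
    expect_equal(row(p)$bitter_perception, "longest")
  }
  # identical estimates share labels; a batch of one is refused
  twin <- list(a = ring_estimate(1, 3), b = ring_estimate(1, 3))
  tl <- classify_taste(twin)
  expect_equal(tl$sweetness[1], tl$sweetness[2])
  expect_error(classify_taste(list(a = ring_estimate(1, 3))), "at least 2")
})

test_that("run_qc grades a batch end to end, deterministically, and isolates failures", {
  cal <- ref_calibration()
  china2ish <- blend_spec(
    c("Steviolbioside" = 0.2, "Stevioside" = 0.5, "Rebaudioside A" = 0.3),
    noise_sigma = 0, extraneous_869_area = 0.09)
  batch <- run_qc(list(
    "RebM" = synth_spectrum("Rebaudioside M", noise_sigma = 0),
    "China2like" = synth_spectrum(china2ish)), cal)
  expect_length(batch$reports, 2)
  expect_length(batch$failures, 0)
  rebm <- batch$reports$RebM
  expect_lt(abs(rebm$rings$ntot_r1 - 6), 0.25)
  expect_false(rebm$adulterant$flag)
  expect_true(batch$reports$China2like$adulterant$flag)
  expect_equal(rebm$taste$sweetness, "highest")
  expect_equal(sum(batch$reports$China2like$carbonyl_composition$fraction), 1,
               tolerance = 1e-9)

  # determinism: identical inputs give identical summaries
  batch2 <- run_qc(list(
    "RebM" = synth_spectrum("Rebaudioside M", noise_sigma = 0),
    "China2like" = synth_spectrum(china2ish)), cal)
  expect_identical(summary(batch), summary(batch2))

  # an unreadable file yields a structured failure, not a crash
  good1 <- withr::local_tempfile(fileext = ".csv")
  good2 <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(synth_spectrum("Rebaudioside A", noise_sigma = 0), good1)
  write_spectrum(synth_spectrum("Stevioside", noise_sigma = 0), good2)
  batch3 <- run_qc(list(a = good1, b = "missing_file.csv", c = good2), cal)
  expect_length(batch3$reports, 2)
  expect_named(batch3$failures, "b")
  expect_match(batch3$failures$b, "not found")
})

test_that("estimated totals rise with the injected total ring count across blends", {
  cal <- ref_calibration()
  fracs <- c(0, 0.25, 0.5, 0.75, 1)
  ntot <- vapply(fracs, function(w) {
    comp <- c("Rubusoside" = 1 - w, "Rebaudioside M" = w)
    comp <- comp[comp > 0]
    b <- if (length(comp) == 1) {
      synth_spectrum(names(comp), noise_sigma = 0)
    } else {
      synth_spectrum(blend_spec(comp, noise_sigma = 0))
    }
    p <- compute_parameters(preprocess(b))
    est <- estimate_rings(p, cal$nu_co, cal$r1, cal$r2)
    est$ntot_r1
  }, numeric(1))
  expect_true(all(diff(ntot) > 0))
})
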