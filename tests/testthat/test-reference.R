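test_that("the compound library holds the twelve elementary glycosides with consistent chemistry", {
  lib <- stevia_compounds()
  expect_equal(nrow(lib), 12)
  expect_equal(anyDuplicated(lib$name), 0)
  expect_equal(lib$rings_total, lib$rings_c19 + lib$rings_c13)
  # printed molecular weights reproduced from the formulas
  for (i in seq_len(nrow(lib))) {
    expect_lt(abs(mw_from_formula(lib$formula[i]) - lib$mw[i]), 0.05)
  }
})

test_that("formula masses use conventional atomic weights and reject bad input", {
  expect_equal(mw_from_formula("C44H70O23"), 967.01, tolerance = 0.02 / 967)
  expect_equal(mw_from_formula("C56H90O33"), 1291.29, tolerance = 0.02 / 1291)
  expect_equal(mw_from_formula("C38H60O17"), 788.87, tolerance = 0.02 / 789)
  expect_equal(mw_from_formula("H2O"), 18.02, tolerance = 0.01 / 18)
  expect_error(mw_from_formula("C6H12N"), "unknown element")
  expect_error(mw_from_formula("c6h12"), "malformed")
})

test_that("compound lookup is case-insensitive, honours the Rebaudioside X alias, and lists valid names", {
  m <- get_compound("Rebaudioside M")
  expect_equal(m$rings_c19, 3)
  expect_equal(m$rings_c13, 3)
  expect_equal(m$mw, 1291.29)
  expect_equal(get_compound("rebaudioside x")$name, "Rebaudioside M")
  r <- get_compound("RUBUSOSIDE")
  expect_equal(c(r$rings_c19, r$rings_c13, r$rings_total), c(1, 1, 2))
  expect_error(get_compound("Sucrose"), "Dulcoside A")
})

test_that("band assignments carry the parameter-defining centers once each, inside their windows", {
  a <- list_assignments()
  expect_true(all(a$center >= a$window_lo & a$center <= a$window_hi))
  for (cc in c(887, 898, 1192, 1204, 1215)) {
    expect_equal(sum(a$center == cc), 1)
  }
  ag <- list_assignments("aglycone_core")
  expect_true(all(c(740, 898, 1204, 1670, 1738) %in% ag$center))
  expect_true(869 %in% list_assignments("extraneous")$center)
  glu <- list_assignments("glucose_ring")
  expect_true(all(glu$window_lo %in% c(850, 1150)))
  cls <- carbonyl_classes()
  expect_equal(cls$center[cls$rings_c19 %in% 0], 1706)
  expect_equal(cls$center[cls$rings_c19 %in% 1], 1719)
  expect_equal(cls$center[cls$class == "linked"], 1738)
})

test_that("generator reference ratios increase strictly with the total ring count", {
  lib <- stevia_compounds()
  o <- order(lib$rings_total, lib$r1_ref)
  expect_true(all(diff(lib$r1_ref[o]) > 0))
  expect_true(all(diff(lib$r2_ref[o]) > 0))
  # between ring classes the ordering is strict regardless of the tie-break
  for (i in seq_len(nrow(lib))) {
    for (j in seq_len(nrow(lib))) {
      if (lib$rings_total[i] > lib$rings_total[j]) {
        expect_gt(lib$r1_ref[i], lib$r1_ref[j])
        expect_gt(lib$r2_ref[i], lib$r2_ref[j])
      }
    }
  }
})

test_that("synthetic spectra are deterministic per seed and carry their injected truth", {
  b <- blend_spec(c("Stevioside" = 0.5, "Rebaudioside A" = 0.5),
                  noise_sigma = 0.005, seed = 42)
  s1 <- synth_spectrum(b)
  s2 <- synth_spectrum(b)
  expect_identical(s1$intensity, s2$intensity)
  s3 <- synth_spectrum(blend_spec(c("Stevioside" = 0.5, "Rebaudioside A" = 0.5),
                                  noise_sigma = 0.005, seed = 43))
  expect_false(identical(s1$intensity, s3$intensity))

  # noiseless pure compound: truth is self-consistent with the band table
  s <- synth_spectrum("Rebaudioside M", noise_sigma = 0)
  tr <- attr(s, "truth")
  a <- function(cc) sum(tr$bands$area[abs(tr$bands$center - cc) < 1e-9])
  expect_equal(a(887) / a(898), tr$r1, tolerance = 1e-6)
  expect_equal((a(1192) + a(1215)) / a(1204), tr$r2, tolerance = 1e-6)
  cls <- carbonyl_classes()
  expect_equal(tr$nu_co, cls$center[cls$rings_c19 %in% 3], tolerance = 1e-9)
  expect_equal(tr$r1, get_compound("Rebaudioside M")$r1_ref)
})

test_that("blend truth interpolates between the pure compounds", {
  r1_st <- attr(synth_spectrum("Stevioside", noise_sigma = 0), "truth")$r1
  r1_ra <- attr(synth_spectrum("Rebaudioside A", noise_sigma = 0), "truth")$r1
  mix <- attr(synth_spectrum(blend_spec(
    c("Stevioside" = 0.5, "Rebaudioside A" = 0.5), noise_sigma = 0)),
    "truth")$r1
  expect_gt(mix, min(r1_st, r1_ra))
  expect_lt(mix, max(r1_st, r1_ra))
  expect_error(blend_spec(c("Stevioside" = 0.5, "Rebaudioside A" = 0.4)),
               "sum to 1")
  expect_error(blend_spec(c("Sucrose" = 1)), "unknown compound")
})

test_that("the full pipeline recovers every compound's injected parameters", {
  # noiseless generator -> preprocess -> window fits -> parameters, for all
  # twelve library compounds (measured values cached by ref_calibration)
  pars <- ref_calibration()$parameters
  lib <- stevia_compounds()
  cls <- carbonyl_classes()
  for (i in seq_len(nrow(lib))) {
    j <- match(lib$name[i], pars$compound)
    expect_lt(abs(pars$r1[j] - lib$r1_ref[i]) / lib$r1_ref[i], 0.01)
    expect_lt(abs(pars$r2[j] - lib$r2_ref[i]) / lib$r2_ref[i], 0.01)
    nu_true <- cls$center[match(lib$rings_c19[i], cls$rings_c19)]
    expect_lt(abs(pars$nu_co[j] - nu_true), 0.2)
  }
})

test_that("the Steviolbioside template carries both carbonyl bands", {
  s <- synth_spectrum("Steviolbioside", noise_sigma = 0)
  tr <- attr(s, "truth")
  co_centers <- tr$bands$center[tr$bands$center >= 1690 & tr$bands$center <= 1760]
  expect_setequal(co_centers, c(1706, 1738))
  expect_equal(tr$nu_co, 1706)  # linked 1738 class excluded
})
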