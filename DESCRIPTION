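Package: steviaQC
Title: Raman Spectroscopic Quality Control of Steviol-Glycoside Sweeteners
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deconvolutes Raman spectra of stevia-based sweeteners into
    Gaussian-Lorentzian (pseudo-Voigt) sub-bands and computes three
    structure-sensitive spectroscopic parameters: the carbonyl stretching
    wavenumber and the areal intensity ratios R1 = I887/I898 and
    R2 = (I1192 + I1215)/I1204. Monotone calibration curves fitted over the
    twelve elementary diterpene glycosides link these parameters to the
    number of glucose rings on the C19 and C13 sides of the steviol aglycone;
    inverting them grades unknown commercial blends (ring counts, C13/C19
    ratio, carbonyl class composition, extraneous-band adulterant flag and
    comparative taste labels). Includes spectrum I/O (CSV/TSV and a JCAMP-DX
    subset), replicate averaging, polynomial baseline subtraction,
    normalization, a reference compound library and a synthetic-spectrum
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
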