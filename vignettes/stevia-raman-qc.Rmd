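---
title: "Raman band deconvolution and ring-count calibration for stevia QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Raman band deconvolution and ring-count calibration for stevia QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steviaQC)
```

## The measurement model

A Raman spectrum of a stevia product is modelled, within each analysis
window, as a sum of pseudo-Voigt sub-bands on top of a smooth background:

$$ I(\nu) \;=\; B(\nu) \;+\; \sum_k h_k \left[ \eta_k L(\nu; \nu_k, w_k)
   + (1-\eta_k)\, G(\nu; \nu_k, w_k) \right] + \varepsilon(\nu), $$

where $L$ and $G$ are unit-height Lorentzian and Gaussian profiles
sharing the center $\nu_k$ and full width at half maximum $w_k$, $h_k$ is
the peak height and $\eta_k \in [0,1]$ the Lorentzian fraction. The
linear-combination pseudo-Voigt (rather than the Gaussian×Lorentzian
product form) is the standard reading of "Gaussian–Lorentzian band
components" in Raman band fitting. The areal intensity of a sub-band has
the closed form

$$ A_k = \eta_k \tfrac{\pi}{2} h_k w_k
       + (1-\eta_k)\, h_k w_k \sqrt{\pi / (4 \ln 2)}, $$

which `band_area()` implements and the test suite checks against
numerical quadrature over the full line (a truncated quadrature range
cannot be used as the oracle: a pure Lorentzian still holds ~0.6% of its
area beyond ±50 FWHM).

Three quantities summarize the glycosylation state of the steviol
aglycone:

* $\nu_{CO}$, the C19=O stretching wavenumber, increasing with the number
  of glucose rings esterified at C19 (more rings raise the energy of the
  vibration). It is computed as the area-weighted mean center of the
  carbonyl sub-bands in 1690–1760 cm⁻¹, *excluding* fitted centers at or
  above 1734 cm⁻¹: the ~1738 cm⁻¹ class is attributed to a carbonyl
  incorporated at a modified C16/C17 site (the Steviolbioside anomaly, a
  molecule with zero C19 rings that nevertheless shows a 1738 cm⁻¹ band),
  and including it would bias the C19 ring count upward. The cutoff is a
  `compute_parameters()` argument.
* $R_1 = A_{887} / A_{898}$, the areal ratio of the glucose C5–O5 stretch
  to the aglycone C11–C12 stretch. The denominator is intrinsic to the
  aglycone, so the ratio scales with the number of glucose rings per
  molecule.
* $R_2 = (A_{1192} + A_{1215}) / A_{1204}$, glucose C–O–H bending modes
  over the aglycone H–C9–C11 stretch — an independent second route to the
  same total ring count. Agreement between the two totals is a built-in
  consistency check (`run_qc` reports both).

## Fixed preprocessing

The pipeline order is fixed: replicate averaging → polynomial baseline
subtraction → normalization to the strongest signal → window fitting.
Normalization deliberately precedes any cropping so that "the strongest
signal in the collected interval" defines the normalizer regardless of
which windows are analysed afterwards; the ratios and $\nu_{CO}$ are
scale-invariant, so normalization affects only reporting, not grading.

The baseline is a least-squares polynomial fitted **only** on anchor
regions assumed band-free, then subtracted everywhere. Defaults: degree 3;
anchors 1550–1600 and 1800–2100 cm⁻¹ plus the first and last 10 cm⁻¹ of
the span — all outside every assigned band window. The exact baseline
settings used with the original instrument software are not recoverable,
which is why reproductions of intensity ratios are tolerance-based, never
bit-exact; the anchors and degree are configurable
(`preprocess_config()`) and echoed into the QC report for provenance.
Negative intensities after subtraction are retained so that fit residuals
stay unbiased. On band-free anchors the operation is idempotent to
numerical precision.

## Band fitting choices

`fit_bands()` runs bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) over $(\nu_k, w_k, h_k)$ per band plus the
$\eta$ block. Numerical conventions:

* **Initialization** is deterministic: seed centers from the assignment
  table (or the user), FWHM 8 cm⁻¹, heights read off the data at the seed
  position. No random restarts, so identical inputs give identical fits.
* **Bounds**: centers constrained to seed ± `center_tol` (default
  8 cm⁻¹; the pipeline narrows this to 45% of the distance to the nearest
  neighbouring seed, floor 2 cm⁻¹, so adjacent assignments cannot swap);
  FWHM in [4, 40] cm⁻¹; heights ≥ 0; $\eta \in [0,1]$.
* **η treatment**: one *shared* η per window by default. With a free η
  per band, two components ~11–14 cm⁻¹ apart have a nearly flat
  area-exchange degeneracy — one band can grow Lorentzian tails while its
  neighbour shrinks at almost no residual cost — which defeats
  percent-level areal accuracy at realistic noise. Sharing η is
  defensible physically, since bands of like moieties in one spectral
  region share broadening mechanisms, and it removes the degeneracy; the
  recovery property test exercises the resulting accuracy. `eta = "free"`
  and fixed numeric η remain available.
* **Degenerate collapse**: two fitted centers within 0.5 cm⁻¹ are merged
  post hoc, areas summed, center area-weighted.
* **Nearest-band lookup** (`areal_intensity_at`): the band closest to the
  target center within a 5 cm⁻¹ tolerance; exact distance ties go to the
  larger area; a missing band is an error naming the target, because the
  aglycone denominators at 898 and 1204 cm⁻¹ must exist in any steviol
  spectrum.
* **Carbonyl window**: fitted over 1640–1780 cm⁻¹ so the C16–C17 stretch
  at 1670 cm⁻¹ is modelled instead of leaking into the carbonyl
  sub-bands. All five class seeds (1706, 1719, 1728, 1733, 1738 cm⁻¹) are
  offered, then *backward elimination* removes the weakest sub-band while
  the refit residual stays at the noise floor. One-shot pruning is not
  enough here: class seeds sit only 5–13 cm⁻¹ apart, and fitting them all
  to a single true band can split it into redundant satellites that each
  carry enough area to survive a fractional-area cut and skew the
  area-weighted carbonyl center.

## Calibration

`fit_calibration()` fits a least-squares quadratic of parameter value
against ring count and checks monotonicity on a 0.01-step grid; if the
quadratic is non-monotone it falls back to isotonic regression
(`stats::isoreg`) with linear interpolation between pooled level means.
The functional form of the original fitting curves is not published;
quadratic-with-fallback is chosen as the simplest form that is robust
with 4–5 ring levels, and the fitted form is recorded in the model for
provenance. Compounds sharing a ring count enter as separate points —
least squares handles the spread. Inversion (`invert()`) solves
`predict(x) = y` by bisection to 1e-6 on the training domain; values
outside the model range clamp to the domain endpoint and raise an
out-of-range flag. Continuous ring estimates are reported as-is (the
published product table itself prints fractional values such as 1.15
rings); reports round to 2 decimals only at print time.

## The synthetic reference library

No measured spectra of the twelve elementary compounds are deposited, so
the package generates them: pseudo-Voigt bands at the assigned centers on
a 150–2150 cm⁻¹ axis with a 0.5 cm⁻¹ step (matching the stated spectral
resolution; the instrument's true digitization is unknown), a gentle cubic
baseline, and i.i.d. Gaussian noise (default σ = 0.005 of the normalized
maximum, about the residual level of a 10-replicate average) from a fixed
seed. Aglycone band areas are constant per molecule; glucose band areas
scale with ring counts; the carbonyl center follows the C19-ring class:
1706 cm⁻¹ (0 rings) and 1719 cm⁻¹ (1 ring) are published anchors, while
1728 and 1733 cm⁻¹ for 2 and 3 rings are interpolations isolated in
`carbonyl_classes()` so they can be re-anchored against a calibrated
instrument. The Steviolbioside template carries both 1706 and 1738 cm⁻¹
carbonyl bands, reproducing the published anomaly. The per-compound
reference ratios `r1_ref`/`r2_ref` are *synthetic conventions* — linear
in the total ring count with small structural offsets, the R2 offsets
0.75× the R1 offsets so the two total-ring routes agree — because the
measured per-compound ratios appear only in figure insets, not as printed
numbers.

Two quirks of the source table are handled explicitly: its second row is
labelled "Steviolbioside" but describes the glucopyranosyl ester
C₃₈H₆₀O₁₈ with one C19 ring — chemically Stevioside — and is recorded
under that name with a provenance note; and Rebaudioside C's rhamnose
ring is counted as a full ring for ratio scaling (its hydroxyl deficit
affects receptor binding, not the ring-counting vibrations modelled
here).

What passing recovery tests do and do not show: they demonstrate that the
deconvolution, calibration and inversion machinery is self-consistent —
injected parameters come back within 1% (ratios), 0.2 cm⁻¹ ($\nu_{CO}$)
and ±0.25 rings on noiseless library spectra, and within 5% areal error
on noisy seeded windows. They cannot validate instrument-specific
effects: real spectra add fluorescence backgrounds beyond a cubic,
temperature and laser-power shifts, detector nonlinearity and bands of
excipients, and the synthetic ratio scale is a convention. For real use,
the calibrations must be re-fitted from measured spectra of the reference
compounds (`fit_calibration()` on measured points); the QC logic is
unchanged.

## Grading unknowns

`run_qc()` applies the full chain per product and, for batches of two or
more, assigns comparative taste labels. The structure→taste rules are:
more total rings → stronger sweetness; lower C13/C19 ratio → faster
sweetness peak; fewer C19 rings → longer bitterness. The published
product gradings, however, coordinate all three labels per product (the
product with the second-lowest ratio still carries the "slowest" label of
its overall quality group), and the per-parameter orderings are not
independently monotone in the printed table. The classifier therefore
partitions the batch into quality groups by gap-clustering the R1-based
total ring count — groups split where consecutive sorted totals differ by
more than 0.2 rings, well above the within-group spread and below the
between-group gaps in the published table — and assigns each group a
coordinated label triple (highest/fastest/shortest, intermediate/slow/
long, lowest/slowest/longest). Ties share labels; a batch of one is
refused, because the labels are comparative superlatives and no absolute
sweetness scale is invented. This reproduces the published grading of the
five commercial products exactly, including the directionality checks
(the top group also has the lowest ratio and the most C19 rings).

The adulterant screen refits the glucose window only when a residual peak
exceeds max(5·MAD of the residual, 0.1% of the window maximum) — below
that the detection would sit in the fit-noise floor — and flags a band
with center within 869 ± 5 cm⁻¹ and at least 1% of the window's fitted
area that no steviol assignment claims. The assignment of that band to an
artificial sweetener is tentative, and the report says so.

## Degenerate inputs and scale conventions

Wavenumber axes are ascending cm⁻¹ everywhere; readers sort on load and
collapse duplicate wavenumbers by mean. Spectra need ≥ 2 points at the
I/O level (round-trip tests use 3-point files), while analysis operations
demand real coverage: ≥ 16 points for a crop window, ≥ 8 per fitted
window, and anchor regions covering ≥ 4·(degree+1) points for the
baseline. Replicates on mismatched axes are linearly resampled onto the
first spectrum's axis over the common overlap. A constant calibration
refuses inversion; an optimizer failure returns the seeds with
`converged = FALSE` rather than crashing; a failing product inside a
batch becomes a structured failure and the batch continues.

## Problem sizes used in the tests

The validation suite runs entirely on generated data at desk scale:
4001-point spectra (150–2150 cm⁻¹ at 0.5 cm⁻¹), a 12-spectrum reference
calibration, and 100 seeded random windows of 2–4 bands for the recovery
property (per-band SNR 60–200, the regime of 10-replicate-averaged
high-resolution spectra — at signal-to-noise ratios near 20, band areas
of overlapping components are not identifiable to 5%, which is one of the
reasons the shared-η default exists).

## Known limitations

* The ring calibrations are only as good as the reference measurements;
  the shipped ones are synthetic and must be re-anchored for any real
  instrument.
* The 2- and 3-ring carbonyl class centers are interpolated, not
  published.
* $\nu_{CO}$ for blends is an area-weighted mean over non-linked
  sub-bands; how the original analysis collapsed several carbonyl
  sub-bands into one "average value" is unstated, so this is a declared
  choice (`linked_cutoff` configurable).
* The taste labels are comparative within a batch only, and implement
  the structure→taste rules, not a sensory panel.
* The adulterant flag detects an unassigned ~869 cm⁻¹ band; it does not
  identify or quantify the adulterant.
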