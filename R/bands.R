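#' Pseudo-Voigt band profile
#'
#' The linear-combination pseudo-Voigt used throughout the package to model
#' Raman sub-bands: a mixture of a Lorentzian and a Gaussian of equal
#' height, sharing the same center and full width at half maximum,
#' \deqn{I(\nu) = h [\eta L(\nu) + (1-\eta) G(\nu)]}
#' with `eta` the Lorentzian fraction. Both components have unit height, so
#' `I(center) = height` for any `eta` and `I(center +/- fwhm/2) = height/2`.
#'
#' @param nu Wavenumbers (cm^-1) at which to evaluate; vectorized.
#' @param center Band center (cm^-1).
#' @param fwhm Full width at half maximum (cm^-1), positive.
#' @param height Peak intensity, non-negative.
#' @param eta Lorentzian fraction in `[0, 1]`.
#' @return Intensity at `nu`.
#' @examples
#' pseudo_voigt(898, center = 898, fwhm = 8, height = 1, eta = 0.3)  # = 1
#' @export
pseudo_voigt <- function(nu, center, fwhm, height, eta) {
  stopifnot(fwhm > 0, height >= 0, eta >= 0, eta <= 1)
  u <- (nu - center) / (fwhm / 2)
  lor <- 1 / (1 + u^2)
  gau <- exp(-log(2) * u^2)
  height * (eta * lor + (1 - eta) * gau)
}

#' Construct a band
#'
#' One pseudo-Voigt component. The integrated (areal) intensity is computed
#' analytically on construction:
#' \deqn{A = \eta \frac{\pi}{2} h w + (1-\eta) h w \sqrt{\pi / (4 \ln 2)}}
#'
#' @inheritParams pseudo_voigt
#' @return An object of class `raman_band`: a list with `center`, `fwhm`,
#'   `height`, `eta`, `area`.
#' @export
band <- function(center, fwhm, height = 1, eta = 0.5) {
  stopifnot(is.finite(center), fwhm > 0, height >= 0, eta >= 0, eta <= 1)
  structure(list(center = center, fwhm = fwhm, height = height, eta = eta,
                 area = band_area(fwhm = fwhm, height = height, eta = eta)),
            class = "raman_band")
}

#' Analytic pseudo-Voigt band area
#'
#' Closed-form integral of the pseudo-Voigt profile over the whole axis:
#' the Lorentzian part contributes `(pi/2) h w`, the Gaussian part
#' `h w sqrt(pi / (4 ln 2))`.
#'
#' @param b Optionally, a [band] object (its stored parameters are used).
#' @inheritParams pseudo_voigt
#' @return The areal intensity (a.u. * cm^-1).
#' @export
band_area <- function(b = NULL, fwhm = b$fwhm, height = b$height, eta = b$eta) {
  stopifnot(fwhm > 0, height >= 0, eta >= 0, eta <= 1)
  eta * (pi / 2) * height * fwhm +
    (1 - eta) * height * fwhm * sqrt(pi / (4 * log(2)))
}

#' @export
print.raman_band <- function(x, ...) {
  cat(sprintf(
    "pseudo-Voigt band: center %.2f cm^-1, FWHM %.2f, height %.4g, eta %.2f, area %.4g\n",
    x$center, x$fwhm, x$height, x$eta, x$area))
  invisible(x)
}

# Sum of pseudo-Voigt components; bands is a data.frame with columns
# center, fwhm, height, eta.
eval_band_model <- function(nu, bands) {
  y <- numeric(length(nu))
  for (i in seq_len(nrow(bands))) {
    y <- y + pseudo_voigt(nu, bands$center[i], bands$fwhm[i],
                          bands$height[i], bands$eta[i])
  }
  y
}

# Normalise heterogeneous seed input (numeric centers, band objects, list of
# bands, or data.frame) to a data.frame(center, fwhm, height, eta) with NA
# for unspecified start values.
as_band_frame <- function(seeds) {
  if (inherits(seeds, "raman_band")) seeds <- list(seeds)
  if (is.numeric(seeds)) {
    return(data.frame(center = as.numeric(seeds), fwhm = NA_real_,
                      height = NA_real_, eta = NA_real_))
  }
  if (is.data.frame(seeds)) {
    out <- data.frame(center = seeds$center)
    out$fwhm <- if ("fwhm" %in% names(seeds)) seeds$fwhm else NA_real_
    out$height <- if ("height" %in% names(seeds)) seeds$height else NA_real_
    out$eta <- if ("eta" %in% names(seeds)) seeds$eta else NA_real_
    return(out)
  }
  if (is.list(seeds)) {
    ok <- vapply(seeds, inherits, logical(1), "raman_band")
    if (all(ok)) {
      return(data.frame(
        center = vapply(seeds, `[[`, numeric(1), "center"),
        fwhm = vapply(seeds, `[[`, numeric(1), "fwhm"),
        height = vapply(seeds, `[[`, numeric(1), "height"),
        eta = vapply(seeds, `[[`, numeric(1), "eta")))
    }
  }
  stop("seeds must be numeric centers, band objects or a data.frame",
       call. = FALSE)
}
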