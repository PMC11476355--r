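# Fixed per-band generator conventions (areas in arbitrary units relative
# to the aglycone denominators at 898 and 1204 cm^-1, which are 1 by
# construction). Aglycone band areas are constant per molecule; glucose
# band areas scale with ring counts through r1_ref/r2_ref.
generator_aglycone_bands <- function() {
  data.frame(
    center = c(740, 898, 1004, 1030, 1075, 1204, 1670),
    area   = c(0.40, 1.00, 0.50, 0.70, 0.60, 1.00, 0.60),
    fwhm   = c(8, 8, 8, 8, 8, 8, 8),
    eta    = 0.5
  )
}

# All bands (center, area, fwhm, eta) for one library compound.
compound_band_table <- function(rec) {
  stopifnot(nrow(rec) == 1)
  ag <- generator_aglycone_bands()
  glu <- data.frame(
    center = c(887, 1192, 1215),
    area   = c(rec$r1_ref, 0.55 * rec$r2_ref, 0.45 * rec$r2_ref),
    fwhm   = 8, eta = 0.5
  )
  cls <- carbonyl_classes()
  co_center <- cls$center[match(rec$rings_c19, cls$rings_c19)]
  if (isTRUE(rec$has_linked_carbonyl)) {
    co <- data.frame(center = c(co_center, 1738),
                     area = c(0.32, 0.18), fwhm = 10, eta = 0.5)
  } else {
    co <- data.frame(center = co_center, area = 0.5, fwhm = 10, eta = 0.5)
  }
  rbind(ag, glu, co)
}

#' Specify a synthetic blend
#'
#' Describes a synthetic stand-in for a commercial stevia blend: weight
#' fractions of elementary glycosides, a smooth polynomial baseline,
#' additive Gaussian noise, and optionally an extraneous band at 869
#' cm^-1 emulating an added artificial sweetener.
#'
#' @param components Named numeric vector of positive weight fractions
#'   summing to 1; names are library compound names.
#' @param baseline Numeric polynomial coefficients (constant first),
#'   evaluated on the axis rescaled to `[-1, 1]`. Default: a gentle cubic.
#' @param noise_sigma Standard deviation of i.i.d. Gaussian noise (a.u.),
#'   default 0.005 (about the residual level of a 10-replicate average of
#'   a normalized spectrum).
#' @param seed Integer RNG seed; the generated spectrum is deterministic
#'   per seed.
#' @param extraneous_869_area Areal intensity of an injected 869 cm^-1
#'   band (default 0 = none).
#' @return An object of class `blend_spec`.
#' @export
blend_spec <- function(components, baseline = c(0.05, 0.02, 0.01, 0.005),
                       noise_sigma = 0.005, seed = 1L,
                       extraneous_869_area = 0) {
  stopifnot(is.numeric(components), !is.null(names(components)),
            all(nzchar(names(components))))
  if (any(components <= 0)) {
    stop("weight fractions must be positive", call. = FALSE)
  }
  if (abs(sum(components) - 1) > 1e-8) {
    stop("weight fractions must sum to 1 (got ", sum(components), ")",
         call. = FALSE)
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  for (nm in names(components)) get_compound(nm)  # validates names
  structure(list(components = components, baseline = as.numeric(baseline),
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 extraneous_869_area = extraneous_869_area),
            class = "blend_spec")
}

#' @export
print.blend_spec <- function(x, ...) {
  cat("Synthetic blend:\n")
  for (nm in names(x$components)) {
    cat(sprintf("  %-16s %.3f\n", nm, x$components[[nm]]))
  }
  cat(sprintf("  noise sigma %.4g, seed %d", x$noise_sigma, x$seed))
  if (x$extraneous_869_area > 0) {
    cat(sprintf(", extraneous 869 cm^-1 band (area %.3g)",
                x$extraneous_869_area))
  }
  cat("\n")
  invisible(x)
}

#' Generate a synthetic Raman spectrum
#'
#' Builds a spectrum as the sum of pseudo-Voigt bands at the assignment
#' centers, with glucose-ring band areas scaled by the compound's ring
#' counts, aglycone band areas constant, and the carbonyl center set by the
#' C19-ring class, superposed on a polynomial baseline with additive
#' Gaussian noise. The injected truth (full band table, R1, R2, nu_CO and
#' ring counts) is attached as `attr(s, "truth")` so recovery by the
#' fitting pipeline can be validated.
#'
#' @param blend A [blend_spec], or a single compound name (treated as a
#'   pure, noiseless-by-default blend via the `...` defaults).
#' @param axis Wavenumber axis; default 150-2150 cm^-1 in 0.5 cm^-1 steps.
#' @param ... When `blend` is a compound name: arguments passed on to
#'   [blend_spec()] (e.g. `noise_sigma`, `seed`, `baseline`).
#' @return A [raman_spectrum] with a `truth` attribute.
#' @examples
#' s <- synth_spectrum("Rebaudioside M", noise_sigma = 0)
#' attr(s, "truth")$r1
#' @export
synth_spectrum <- function(blend, axis = seq(150, 2150, by = 0.5), ...) {
  if (is.character(blend)) {
    blend <- blend_spec(stats::setNames(1, blend), ...)
  }
  stopifnot(inherits(blend, "blend_spec"))
  axis <- as.numeric(axis)
  # blend band table: per-compound areas weighted by fraction; identical
  # centers accumulate
  tabs <- lapply(names(blend$components), function(nm) {
    tb <- compound_band_table(get_compound(nm))
    tb$area <- tb$area * blend$components[[nm]]
    tb
  })
  bands <- do.call(rbind, tabs)
  agg <- stats::aggregate(area ~ center + fwhm + eta, data = bands, FUN = sum)
  bands <- agg[order(agg$center), c("center", "fwhm", "eta", "area")]
  if (blend$extraneous_869_area > 0) {
    bands <- rbind(bands, data.frame(center = 869, fwhm = 8, eta = 0.5,
                                     area = blend$extraneous_869_area))
    bands <- bands[order(bands$center), ]
  }
  bands$height <- bands$area / vapply(seq_len(nrow(bands)), function(i) {
    band_area(fwhm = bands$fwhm[i], height = 1, eta = bands$eta[i])
  }, numeric(1))
  rownames(bands) <- NULL

  y <- eval_band_model(axis, bands)
  t0 <- (axis - mean(range(axis))) / (diff(range(axis)) / 2)
  y <- y + as.numeric(outer(t0, seq_along(blend$baseline) - 1, `^`) %*%
                        blend$baseline)
  if (blend$noise_sigma > 0) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(blend$seed)
    y <- y + stats::rnorm(length(axis), 0, blend$noise_sigma)
  }

  truth <- generator_truth(bands, blend)
  s <- raman_spectrum(axis, y, meta = list(
    synthetic = TRUE,
    components = paste(sprintf("%s:%.3f", names(blend$components),
                               blend$components), collapse = ";"),
    seed = blend$seed))
  attr(s, "truth") <- truth
  s
}

# Injected truth for a generated blend: the parameter values an ideal
# analysis would recover.
generator_truth <- function(bands, blend) {
  lib <- stevia_compounds()
  w <- blend$components
  idx <- match(tolower(names(w)), tolower(lib$name))
  area_at <- function(center) {
    hit <- abs(bands$center - center) < 1e-9
    if (any(hit)) sum(bands$area[hit]) else 0
  }
  co <- bands[bands$center >= 1690 & bands$center <= 1760 &
                abs(bands$center - 869) > 1e-9, , drop = FALSE]
  co_main <- co[co$center < 1734, , drop = FALSE]
  nu_co <- if (nrow(co_main) && sum(co_main$area) > 0) {
    sum(co_main$center * co_main$area) / sum(co_main$area)
  } else {
    NA_real_
  }
  list(
    bands = bands,
    r1 = area_at(887) / area_at(898),
    r2 = (area_at(1192) + area_at(1215)) / area_at(1204),
    nu_co = nu_co,
    rings_c19 = sum(w * lib$rings_c19[idx]),
    rings_total = sum(w * (lib$rings_c19[idx] + lib$rings_c13[idx])),
    components = w
  )
}
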