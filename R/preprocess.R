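#' Preprocessing configuration
#'
#' Fixed preprocessing criteria applied identically to every spectrum:
#' polynomial baseline subtraction anchored on band-free regions, then
#' normalization to the strongest signal in the collected interval.
#'
#' @param baseline_degree Integer in `[0, 6]`; degree of the baseline
#'   polynomial (default 3).
#' @param anchor_regions List of length-2 numeric vectors giving wavenumber
#'   intervals assumed band-free. `NULL` (default) uses 1550-1600 and
#'   1800-2100 cm^-1 plus the first and last 10 cm^-1 of the spectrum span,
#'   all outside every assigned band window.
#' @param normalization `"max"` (divide by the maximum intensity) or
#'   `"none"`.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(baseline_degree = 3L, anchor_regions = NULL,
                              normalization = c("max", "none")) {
  baseline_degree <- as.integer(baseline_degree)
  if (is.na(baseline_degree) || baseline_degree < 0L || baseline_degree > 6L) {
    stop("baseline_degree must be an integer in [0, 6]", call. = FALSE)
  }
  normalization <- match.arg(normalization)
  if (!is.null(anchor_regions)) {
    ok <- is.list(anchor_regions) &&
      all(vapply(anchor_regions, function(r) {
        is.numeric(r) && length(r) == 2 && r[1] < r[2]
      }, logical(1)))
    if (!ok) {
      stop("anchor_regions must be a list of increasing length-2 intervals",
           call. = FALSE)
    }
  }
  structure(list(baseline_degree = baseline_degree,
                 anchor_regions = anchor_regions,
                 normalization = normalization),
            class = "preprocess_config")
}

#' @export
print.preprocess_config <- function(x, ...) {
  cat("Preprocessing config:\n")
  cat("  baseline degree:", x$baseline_degree, "\n")
  if (is.null(x$anchor_regions)) {
    cat("  anchors: default (1550-1600, 1800-2100, span edges)\n")
  } else {
    cat("  anchors:", paste(vapply(x$anchor_regions, function(r)
      sprintf("%.0f-%.0f", r[1], r[2]), character(1)), collapse = ", "), "\n")
  }
  cat("  normalization:", x$normalization, "\n")
  invisible(x)
}

default_anchor_regions <- function(s) {
  lo <- min(s$wavenumber); hi <- max(s$wavenumber)
  regions <- list(c(lo, lo + 10), c(hi - 10, hi))
  for (r in list(c(1550, 1600), c(1800, 2100))) {
    if (r[1] >= lo && r[2] <= hi) regions <- c(regions, list(r))
  }
  regions
}

#' Subtract a polynomial baseline
#'
#' Least-squares fits a polynomial of `cfg$baseline_degree` to the intensity
#' at the anchor-region points only, then subtracts it everywhere. Negative
#' intensities after subtraction are retained so fit residuals stay
#' unbiased. The operation is idempotent when the anchors are band-free.
#'
#' @param s A [raman_spectrum].
#' @param cfg A [preprocess_config].
#' @return A baseline-corrected [raman_spectrum];
#'   `meta$baseline_removed = TRUE`.
#' @export
subtract_baseline <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "raman_spectrum"))
  anchors <- cfg$anchor_regions
  if (is.null(anchors)) anchors <- default_anchor_regions(s)
  lo <- min(s$wavenumber); hi <- max(s$wavenumber)
  for (r in anchors) {
    if (r[1] < lo - 1e-9 || r[2] > hi + 1e-9) {
      stop(sprintf("anchor region %.1f-%.1f outside spectrum span %.1f-%.1f",
                   r[1], r[2], lo, hi), call. = FALSE)
    }
  }
  in_anchor <- Reduce(`|`, lapply(anchors, function(r) {
    s$wavenumber >= r[1] & s$wavenumber <= r[2]
  }))
  need <- 4L * (cfg$baseline_degree + 1L)
  if (sum(in_anchor) < need) {
    stop("anchor regions cover ", sum(in_anchor),
         " points; need at least ", need, call. = FALSE)
  }
  # centred/scaled axis keeps the Vandermonde system well conditioned
  x0 <- (s$wavenumber - mean(s$wavenumber)) / (diff(range(s$wavenumber)) / 2)
  X <- outer(x0[in_anchor], 0:cfg$baseline_degree, `^`)
  beta <- qr.coef(qr(X), s$intensity[in_anchor])
  base <- as.numeric(outer(x0, 0:cfg$baseline_degree, `^`) %*% beta)
  out <- s
  out$intensity <- s$intensity - base
  out$meta$baseline_removed <- TRUE
  out$meta$baseline_degree <- cfg$baseline_degree
  out
}

#' Normalize a spectrum to its strongest signal
#'
#' Divides intensities by the maximum over the collected interval so that
#' the strongest band has intensity exactly 1. Idempotent.
#'
#' @param s A [raman_spectrum] with positive maximum intensity.
#' @return A normalized [raman_spectrum]; `meta$normalized = "max"`.
#' @export
normalize_to_max <- function(s) {
  stopifnot(inherits(s, "raman_spectrum"))
  m <- max(s$intensity)
  if (m <= 0) stop("cannot normalize: maximum intensity is not positive",
                   call. = FALSE)
  out <- s
  out$intensity <- s$intensity / m
  out$meta$normalized <- "max"
  out
}

#' Crop a spectrum to a wavenumber window
#'
#' Keeps the points with wavenumber in `[window[1], window[2]]` inclusive.
#'
#' @param s A [raman_spectrum].
#' @param window Length-2 numeric interval in cm^-1.
#' @return The cropped [raman_spectrum].
#' @export
crop_spectrum <- function(s, window) {
  stopifnot(inherits(s, "raman_spectrum"),
            is.numeric(window), length(window) == 2, window[1] < window[2])
  keep <- s$wavenumber >= window[1] & s$wavenumber <= window[2]
  if (sum(keep) < 16) {
    stop(sprintf(
      "window %.1f-%.1f overlaps the axis in only %d points (need >= 16)",
      window[1], window[2], sum(keep)), call. = FALSE)
  }
  out <- s
  out$wavenumber <- s$wavenumber[keep]
  out$intensity <- s$intensity[keep]
  out
}

#' Preprocess a spectrum for band fitting
#'
#' Applies the fixed order baseline subtraction -> normalization.
#' Normalization always uses the full collected interval, which is why
#' cropping (see [crop_spectrum]) is deliberately not part of this step:
#' cropping first would change the normalizer.
#'
#' @param s A [raman_spectrum] (already replicate-averaged if applicable).
#' @param cfg A [preprocess_config].
#' @return The preprocessed [raman_spectrum].
#' @export
preprocess <- function(s, cfg = preprocess_config()) {
  s <- subtract_baseline(s, cfg)
  if (cfg$normalization == "max") s <- normalize_to_max(s)
  s
}
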