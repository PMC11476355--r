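#' Fit a monotone calibration curve
#'
#' Least-squares fits a quadratic of the spectroscopic parameter (carbonyl
#' wavenumber, R1 or R2) against ring count over the elementary-compound
#' points. If the quadratic is not non-decreasing on the domain (checked on
#' a 0.01-step grid), the fit falls back to isotonic regression with linear
#' interpolation between the pooled means, which is monotone by
#' construction. Replicated x values (several compounds share a ring
#' count) are kept as separate points.
#'
#' @param points A data.frame with columns `x` (ring count) and `y`
#'   (parameter value); a `compound` column is carried along if present.
#' @param parameter One of `"nu_co"`, `"R1"`, `"R2"` (label only).
#' @return An object of class `raman_calibration`: `parameter`, `form`
#'   (`"quadratic"` or `"isotonic_linear"`), `coefficients` or `knots`,
#'   `domain`, `fit_rms`, and the training `points` for provenance.
#' @seealso [predict.raman_calibration()], [invert()]
#' @export
fit_calibration <- function(points, parameter = c("nu_co", "R1", "R2")) {
  parameter <- match.arg(parameter)
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  x <- as.numeric(points$x); y <- as.numeric(points$y)
  if (anyNA(x) || anyNA(y) || !all(is.finite(c(x, y)))) {
    stop("calibration points must be finite", call. = FALSE)
  }
  if (length(unique(x)) < 3) {
    stop("need at least 3 distinct ring-count levels, got ",
         length(unique(x)), call. = FALSE)
  }
  constant_y <- (max(y) - min(y)) < 1e-12
  if (constant_y) {
    warning("all parameter values identical; calibration is constant and ",
            "cannot be inverted")
  }
  domain <- range(x)
  grid <- seq(domain[1], domain[2], by = 0.01)

  qfit <- stats::lm(y ~ x + I(x^2))
  beta <- stats::coef(qfit)
  qpred <- function(z) beta[1] + beta[2] * z + beta[3] * z^2
  monotone <- all(diff(qpred(grid)) >= -1e-12)

  if (monotone && !constant_y) {
    form <- "quadratic"
    fit_rms <- sqrt(mean(stats::residuals(qfit)^2))
    model <- list(coefficients = unname(beta))
  } else {
    form <- "isotonic_linear"
    # pool replicated x levels, then isotonic regression on the means
    xs <- sort(unique(x))
    ym <- vapply(xs, function(v) mean(y[x == v]), numeric(1))
    iso <- stats::isoreg(xs, ym)
    knots <- data.frame(x = xs, y = iso$yf)
    f <- stats::approxfun(knots$x, knots$y, rule = 2)
    fit_rms <- sqrt(mean((y - f(x))^2))
    model <- list(knots = knots)
  }
  structure(
    c(list(parameter = parameter, form = form, domain = domain,
           fit_rms = fit_rms, constant = constant_y,
           points = points),
      model),
    class = "raman_calibration")
}

#' @export
print.raman_calibration <- function(x, ...) {
  cat(sprintf("Calibration model for %s: %s on [%g, %g] rings\n",
              x$parameter, x$form, x$domain[1], x$domain[2]))
  if (x$form == "quadratic") {
    cat(sprintf("  y = %.6g + %.6g x + %.6g x^2\n",
                x$coefficients[1], x$coefficients[2], x$coefficients[3]))
  } else {
    cat("  knots:\n")
    print(x$knots)
  }
  cat(sprintf("  fit RMS: %.4g (%d training points)\n",
              x$fit_rms, nrow(x$points)))
  invisible(x)
}

#' @export
coef.raman_calibration <- function(object, ...) {
  if (object$form == "quadratic") object$coefficients else object$knots
}

#' Evaluate a calibration curve
#'
#' @param object A `raman_calibration`.
#' @param x Ring counts at which to evaluate (within the training domain
#'   +/- 0.5; evaluation outside the domain is clamped and flagged).
#' @param ... Unused.
#' @return Numeric parameter values; attribute `extrapolated` is a logical
#'   vector marking clamped evaluations.
#' @export
predict.raman_calibration <- function(object, x, ...) {
  x <- as.numeric(x)
  extrap <- x < object$domain[1] | x > object$domain[2]
  if (any(x < object$domain[1] - 0.5 | x > object$domain[2] + 0.5)) {
    stop("evaluation more than 0.5 rings outside the calibration domain",
         call. = FALSE)
  }
  xc <- pmin(pmax(x, object$domain[1]), object$domain[2])
  out <- if (object$form == "quadratic") {
    b <- object$coefficients
    b[1] + b[2] * xc + b[3] * xc^2
  } else {
    stats::approx(object$knots$x, object$knots$y, xout = xc, rule = 2)$y
  }
  attr(out, "extrapolated") <- extrap
  out
}

#' Invert a calibration curve
#'
#' Solves `predict(model, x) = y` for the ring count by bisection on the
#' training domain to 1e-6. Parameter values below (above) the model range
#' are clamped to the lower (upper) domain endpoint and flagged.
#'
#' @param m A monotone `raman_calibration`.
#' @param y Parameter value(s) to invert.
#' @return Continuous ring count(s); attribute `out_of_range` flags clamped
#'   inversions.
#' @export
invert <- function(m, y) UseMethod("invert")

#' @export
invert.raman_calibration <- function(m, y) {
  if (isTRUE(m$constant)) {
    stop("inversion undefined: calibration model is constant", call. = FALSE)
  }
  y <- as.numeric(y)
  lo <- m$domain[1]; hi <- m$domain[2]
  f <- function(z) as.numeric(predict(m, z))
  ylo <- f(lo); yhi <- f(hi)
  out <- numeric(length(y)); oor <- logical(length(y))
  for (i in seq_along(y)) {
    if (y[i] <= ylo) {
      out[i] <- lo; oor[i] <- y[i] < ylo - 1e-12
    } else if (y[i] >= yhi) {
      out[i] <- hi; oor[i] <- y[i] > yhi + 1e-12
    } else {
      out[i] <- stats::uniroot(function(z) f(z) - y[i], lower = lo,
                               upper = hi, tol = 1e-9)$root
    }
  }
  attr(out, "out_of_range") <- oor
  out
}

#' @export
plot.raman_calibration <- function(x, ...) {
  grid <- seq(x$domain[1], x$domain[2], length.out = 200)
  yy <- as.numeric(predict(x, grid))
  graphics::plot(x$points$x, x$points$y, pch = 19,
                 xlab = "Number of glucose rings",
                 ylab = x$parameter, ...)
  graphics::lines(grid, yy, col = "blue")
  invisible(x)
}

#' Calibrate the three curves from the synthetic reference library
#'
#' Generates a noiseless spectrum for each of the twelve elementary
#' glycosides, runs the full preprocessing and band-fitting pipeline to
#' measure nu_CO, R1 and R2, and fits the three monotone calibration
#' curves: nu_CO against C19-side rings, R1 and R2 against total rings.
#' With spectra from a real instrument, build the `points` data.frames from
#' measured parameters instead and call [fit_calibration()] directly.
#'
#' @param noise_sigma Noise level for the library spectra (default 0,
#'   i.e. noiseless).
#' @param seed RNG seed used when `noise_sigma > 0`.
#' @return A list with elements `nu_co`, `r1`, `r2` (each a
#'   `raman_calibration`) and `parameters` (the per-compound measured
#'   values).
#' @export
calibrate_reference <- function(noise_sigma = 0, seed = 1L) {
  lib <- stevia_compounds()
  rows <- lapply(seq_len(nrow(lib)), function(i) {
    s <- synth_spectrum(lib$name[i], noise_sigma = noise_sigma, seed = seed + i)
    p <- compute_parameters(preprocess(s))
    data.frame(compound = lib$name[i], rings_c19 = lib$rings_c19[i],
               rings_total = lib$rings_total[i],
               nu_co = p$nu_co, r1 = p$r1, r2 = p$r2)
  })
  pars <- do.call(rbind, rows)
  list(
    nu_co = fit_calibration(
      data.frame(compound = pars$compound, x = pars$rings_c19, y = pars$nu_co),
      "nu_co"),
    r1 = fit_calibration(
      data.frame(compound = pars$compound, x = pars$rings_total, y = pars$r1),
      "R1"),
    r2 = fit_calibration(
      data.frame(compound = pars$compound, x = pars$rings_total, y = pars$r2),
      "R2"),
    parameters = pars
  )
}

#' Serialize calibration models to JSON
#'
#' @param cal A single `raman_calibration` or the list returned by
#'   [calibrate_reference()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(cal, path) {
  strip <- function(m) {
    stopifnot(inherits(m, "raman_calibration"))
    out <- unclass(m)
    out$points <- as.list(out$points)
    out
  }
  obj <- if (inherits(cal, "raman_calibration")) {
    list(models = list(strip(cal)))
  } else {
    list(models = lapply(Filter(function(e) inherits(e, "raman_calibration"),
                                cal), strip))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read calibration models written by [write_calibration()]
#'
#' @param path JSON path.
#' @return A named list of `raman_calibration` objects.
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rebuild <- function(m) {
    m$domain <- as.numeric(m$domain)
    m$points <- as.data.frame(m$points)
    if (!is.null(m$coefficients)) m$coefficients <- as.numeric(m$coefficients)
    if (!is.null(m$knots)) m$knots <- as.data.frame(m$knots)
    structure(m, class = "raman_calibration")
  }
  lapply(obj$models, rebuild)
}
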