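#' Construct a Raman spectrum
#'
#' A `raman_spectrum` is the package's universal currency: a strictly
#' increasing wavenumber axis (cm^-1), an intensity vector of equal length
#' (arbitrary units), and free-form metadata.
#'
#' @param wavenumber Numeric vector of Raman shifts in cm^-1, strictly
#'   increasing after sorting; at least 2 points (analysis operations such
#'   as [crop_spectrum()] and [fit_bands()] demand denser coverage).
#' @param intensity Numeric vector of intensities, same length, all finite.
#' @param meta Named list of metadata (sample name, replicate id,
#'   normalization state, ...).
#' @return An object of class `raman_spectrum`.
#' @examples
#' s <- raman_spectrum(seq(100, 200, by = 1), rnorm(101) + 10)
#' s
#' @export
raman_spectrum <- function(wavenumber, intensity, meta = list()) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity)) {
    stop("wavenumber and intensity must have equal length", call. = FALSE)
  }
  if (anyNA(wavenumber) || anyNA(intensity) ||
      !all(is.finite(wavenumber)) || !all(is.finite(intensity))) {
    stop("wavenumber and intensity must be finite and free of NA", call. = FALSE)
  }
  ord <- order(wavenumber)
  wavenumber <- wavenumber[ord]
  intensity <- intensity[ord]
  # collapse duplicate wavenumbers by mean intensity
  if (anyDuplicated(wavenumber)) {
    intensity <- as.numeric(tapply(intensity, wavenumber, mean))
    wavenumber <- sort(unique(wavenumber))
  }
  if (length(wavenumber) < 2) {
    stop("degenerate input: a spectrum needs at least 2 points, got ",
         length(wavenumber), call. = FALSE)
  }
  structure(
    list(wavenumber = wavenumber, intensity = intensity,
         meta = as.list(meta)),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("Raman spectrum: %d points, %.1f-%.1f cm^-1\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(x$intensity), max(x$intensity)))
  if (length(x$meta)) {
    keys <- names(x$meta)
    vals <- vapply(x$meta, function(v) paste(format(v), collapse = ","),
                   character(1))
    cat("  meta:", paste(sprintf("%s=%s", keys, vals), collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.raman_spectrum <- function(x, ...) {
  data.frame(wavenumber = x$wavenumber, intensity = x$intensity)
}

#' @export
plot.raman_spectrum <- function(x, ..., type = "l",
                                xlab = expression(paste("Raman shift (", cm^-1, ")")),
                                ylab = "Intensity (a.u.)") {
  graphics::plot(x$wavenumber, x$intensity, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Read a Raman spectrum from disk
#'
#' Supported formats: two-column CSV/TSV with an optional
#' `wavenumber,intensity` header, and a JCAMP-DX subset (single-block AFFN
#' `##XYDATA=(X++(Y..Y))`). Rows are sorted by ascending wavenumber on load;
#' duplicated wavenumbers are collapsed by mean.
#'
#' @param path Path to the file.
#' @param format One of `"csv"`, `"tsv"`, `"jcamp"`; `"auto"` (default)
#'   guesses from the file extension (`.jdx`/`.dx` are JCAMP, `.tsv`/`.txt`
#'   are TSV, anything else CSV).
#' @return A [raman_spectrum].
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "tsv", "jcamp")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, jdx = , dx = "jcamp", tsv = , txt = "tsv", "csv")
  }
  if (format == "jcamp") {
    return(read_jcamp(path))
  }
  sep <- if (format == "tsv") "\t" else ","
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("format error in ", path, ": empty file", call. = FALSE)
  start <- 1L
  first <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  if (is.na(suppressWarnings(as.numeric(first[1])))) start <- 2L  # header line
  if (start > length(lines)) {
    stop("format error in ", path, ": no data rows", call. = FALSE)
  }
  rows <- strsplit(lines[seq(start, length(lines))], sep, fixed = TRUE)
  bad <- which(lengths(rows) < 2)
  if (length(bad)) {
    stop("format error in ", path, " at line ", start + bad[1] - 1L,
         ": expected two columns", call. = FALSE)
  }
  xs <- suppressWarnings(as.numeric(vapply(rows, `[`, character(1), 1L)))
  ys <- suppressWarnings(as.numeric(vapply(rows, `[`, character(1), 2L)))
  bad <- which(is.na(xs) | is.na(ys))
  if (length(bad)) {
    stop("format error in ", path, " at line ", start + bad[1] - 1L,
         ": non-numeric value '", lines[start + bad[1] - 1L], "'", call. = FALSE)
  }
  raman_spectrum(xs, ys, meta = list(source = path))
}

#' Write a Raman spectrum to disk
#'
#' Values are written with enough digits that
#' `read_spectrum(write_spectrum(s))` reproduces `s` to better than 1e-9
#' relative.
#'
#' @param s A [raman_spectrum].
#' @param path Output path.
#' @param format One of `"csv"`, `"tsv"`, `"jcamp"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, format = c("csv", "tsv", "jcamp")) {
  stopifnot(inherits(s, "raman_spectrum"))
  format <- match.arg(format)
  if (format == "jcamp") {
    write_jcamp(s, path)
    return(invisible(path))
  }
  sep <- if (format == "tsv") "\t" else ","
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot write to ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  on.exit(close(con))
  writeLines(paste("wavenumber", "intensity", sep = sep), con)
  writeLines(paste(sprintf("%.12g", s$wavenumber),
                   sprintf("%.12g", s$intensity), sep = sep), con)
  invisible(path)
}

# JCAMP-DX subset: single block, AFFN-encoded ##XYDATA=(X++(Y..Y)).
read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  labels <- grepl("^##", lines)
  get_field <- function(name) {
    hit <- grep(paste0("^##", name, "\\s*="), lines, ignore.case = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^##", name, "\\s*=\\s*"), "", lines[hit[1]], ignore.case = TRUE)
  }
  xy_at <- grep("^##XYDATA\\s*=", lines, ignore.case = TRUE)
  if (!length(xy_at)) {
    stop("format error in ", path, ": no ##XYDATA block", call. = FALSE)
  }
  form <- toupper(gsub("\\s", "", sub("^##XYDATA\\s*=", "", lines[xy_at[1]],
                                      ignore.case = TRUE)))
  if (form != "(X++(Y..Y))") {
    stop("format error in ", path, ": unsupported XYDATA form '", form,
         "' (only (X++(Y..Y)) AFFN is supported)", call. = FALSE)
  }
  end_at <- grep("^##END", lines[(xy_at[1] + 1):length(lines)],
                 ignore.case = TRUE)
  last <- if (length(end_at)) xy_at[1] + end_at[1] - 1L else length(lines)
  data_lines <- lines[seq(xy_at[1] + 1L, last)]
  data_lines <- data_lines[!grepl("^##", data_lines) & nzchar(trimws(data_lines))]
  xfac <- suppressWarnings(as.numeric(get_field("XFACTOR"))); if (is.na(xfac)) xfac <- 1
  yfac <- suppressWarnings(as.numeric(get_field("YFACTOR"))); if (is.na(yfac)) yfac <- 1
  firstx <- suppressWarnings(as.numeric(get_field("FIRSTX")))
  lastx <- suppressWarnings(as.numeric(get_field("LASTX")))
  npts <- suppressWarnings(as.numeric(get_field("NPOINTS")))
  dx <- if (!is.na(firstx) && !is.na(lastx) && !is.na(npts) && npts > 1) {
    (lastx - firstx) / (npts - 1)
  } else {
    NA_real_
  }
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_along(data_lines)) {
    toks <- strsplit(trimws(data_lines[i]), "[\\s,]+", perl = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(toks))
    if (anyNA(v) || length(v) < 2) {
      stop("format error in ", path, " at XYDATA line ", i,
           ": non-AFFN content '", data_lines[i], "'", call. = FALSE)
    }
    x0 <- v[1] * xfac
    yv <- v[-1] * yfac
    step <- if (!is.na(dx)) dx else {
      stop("format error in ", path,
           ": FIRSTX/LASTX/NPOINTS needed to infer the x step", call. = FALSE)
    }
    xs <- c(xs, x0 + step * (seq_along(yv) - 1))
    ys <- c(ys, yv)
  }
  raman_spectrum(xs, ys, meta = list(source = path,
                                     title = get_field("TITLE")))
}

write_jcamp <- function(s, path) {
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot write to ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  on.exit(close(con))
  x <- s$wavenumber; y <- s$intensity
  n <- length(x)
  steps <- diff(x)
  if (n > 1 && (max(steps) - min(steps)) > 1e-6 * mean(steps)) {
    stop("JCAMP (X++(Y..Y)) requires an evenly spaced axis; ",
         "write this spectrum as csv/tsv instead", call. = FALSE)
  }
  hdr <- c(
    sprintf("##TITLE=%s", if (!is.null(s$meta$title)) s$meta$title else "Raman spectrum"),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=RAMAN SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ARBITRARY UNITS",
    "##XFACTOR=1",
    "##YFACTOR=1",
    sprintf("##FIRSTX=%.12g", x[1]),
    sprintf("##LASTX=%.12g", x[n]),
    sprintf("##NPOINTS=%d", n),
    "##XYDATA=(X++(Y..Y))"
  )
  writeLines(hdr, con)
  per_line <- 4L
  idx <- seq(1, n, by = per_line)
  for (i in idx) {
    j <- min(i + per_line - 1L, n)
    writeLines(paste(c(sprintf("%.12g", x[i]), sprintf("%.12g", y[i:j])),
                     collapse = " "), con)
  }
  writeLines("##END=", con)
  invisible(path)
}

#' Average replicate spectra
#'
#' Pointwise arithmetic mean of replicate spectra, the standard first step
#' when several spectra are collected at random sample locations. Axes that
#' agree within 1e-6 cm^-1 are used as-is; otherwise every replicate is
#' linearly resampled onto the first spectrum's axis, restricted to the
#' common overlap.
#'
#' @param spectra A list of [raman_spectrum] objects (at least one).
#' @return A [raman_spectrum]; `meta$n_replicates` records the count.
#' @export
average_replicates <- function(spectra) {
  if (!is.list(spectra) || !length(spectra)) {
    stop("need at least one spectrum to average", call. = FALSE)
  }
  if (inherits(spectra, "raman_spectrum")) spectra <- list(spectra)
  ok <- vapply(spectra, inherits, logical(1), "raman_spectrum")
  if (!all(ok)) stop("all elements must be raman_spectrum objects", call. = FALSE)
  ref <- spectra[[1]]
  same_axis <- vapply(spectra, function(s) {
    length(s$wavenumber) == length(ref$wavenumber) &&
      max(abs(s$wavenumber - ref$wavenumber)) <= 1e-6
  }, logical(1))
  if (all(same_axis)) {
    axis <- ref$wavenumber
    mat <- vapply(spectra, function(s) s$intensity, numeric(length(axis)))
  } else {
    lo <- max(vapply(spectra, function(s) min(s$wavenumber), numeric(1)))
    hi <- min(vapply(spectra, function(s) max(s$wavenumber), numeric(1)))
    if (hi <= lo) stop("replicate axes do not overlap", call. = FALSE)
    axis <- ref$wavenumber[ref$wavenumber >= lo & ref$wavenumber <= hi]
    if (length(axis) < 16) {
      stop("replicate axis overlap has fewer than 16 points", call. = FALSE)
    }
    mat <- vapply(spectra, function(s) {
      stats::approx(s$wavenumber, s$intensity, xout = axis)$y
    }, numeric(length(axis)))
  }
  raman_spectrum(axis, rowMeans(mat),
                 meta = c(ref$meta, list(n_replicates = length(spectra))))
}
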