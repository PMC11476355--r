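# Per-seed center tolerance: never beyond `cap`, never more than 45% of the
# gap to the nearest neighbouring seed (keeps neighbouring bands from
# swapping), floor of 2 cm^-1.
seed_center_tol <- function(centers, cap = 8) {
  n <- length(centers)
  if (n == 1) return(cap)
  gaps <- vapply(seq_len(n), function(i) {
    min(abs(centers[i] - centers[-i]))
  }, numeric(1))
  pmax(pmin(cap, 0.45 * gaps), 2)
}

#' Compute the three Raman QC parameters of a spectrum
#'
#' Fits the three analysis windows of a preprocessed spectrum with
#' pseudo-Voigt sub-bands seeded from the assignment table and computes:
#' \itemize{
#'   \item `r1 = A(887) / A(898)` — areal ratio of the glucose C5-O5
#'     stretch to the aglycone C11-C12 stretch (850-950 cm^-1 window);
#'   \item `r2 = (A(1192) + A(1215)) / A(1204)` — areal ratio of the
#'     glucose C-O-H bends to the aglycone H-C9-C11 stretch (1150-1250
#'     cm^-1 window);
#'   \item `nu_co` — the area-weighted mean center of the carbonyl
#'     sub-bands in 1690-1760 cm^-1, excluding the linked-carbonyl class
#'     (fitted centers at or above `linked_cutoff`), which is attributed to
#'     a modified C16/C17 site rather than to C19 glycosylation.
#' }
#' The carbonyl region is fitted over 1640-1780 cm^-1 so that the
#' neighbouring C16-C17 stretch at 1670 cm^-1 is modelled rather than
#' leaking into the carbonyl sub-bands; fitting is done in two passes, with
#' sub-bands below 1% of the window area pruned between passes.
#'
#' @param s A preprocessed [raman_spectrum] covering 850-950, 1150-1250 and
#'   1690-1760 cm^-1.
#' @param assignments Band assignment table, see [list_assignments()].
#' @param linked_cutoff Fitted carbonyl centers at or above this wavenumber
#'   (default 1734 cm^-1) are treated as linked carbonyl and excluded from
#'   `nu_co`.
#' @return An object of class `raman_parameters`: `nu_co`, `r1`, `r2`,
#'   `window_fits` (named list of `band_fit`: glucose, bending, carbonyl).
#' @export
compute_parameters <- function(s, assignments = list_assignments(),
                               linked_cutoff = 1734) {
  stopifnot(inherits(s, "raman_spectrum"))
  span <- range(s$wavenumber)
  for (w in list(c(850, 950), c(1150, 1250), c(1690, 1760))) {
    if (span[1] > w[1] || span[2] < w[2]) {
      stop(sprintf("spectrum does not cover the %d-%d cm^-1 window",
                   w[1], w[2]), call. = FALSE)
    }
  }
  glu_seeds <- c(887, 898)
  bend_seeds <- c(1192, 1204, 1215)
  cls <- carbonyl_classes()
  co_seeds <- sort(unique(c(1670, cls$center)))

  fit_glu <- fit_bands(s, c(850, 950), glu_seeds,
                       center_tol = seed_center_tol(glu_seeds))
  fit_bend <- fit_bands(s, c(1150, 1250), bend_seeds,
                        center_tol = seed_center_tol(bend_seeds))
  fit_co <- fit_carbonyl_window(s, co_seeds)

  a887 <- areal_intensity_at(fit_glu, 887, tol = 5)
  a898 <- tryCatch(areal_intensity_at(fit_glu, 898, tol = 5),
                   error = function(e) {
                     stop("missing band: the aglycone 898 cm^-1 denominator ",
                          "band was not found", call. = FALSE)
                   })
  a1192 <- areal_intensity_at(fit_bend, 1192, tol = 5)
  a1204 <- tryCatch(areal_intensity_at(fit_bend, 1204, tol = 5),
                    error = function(e) {
                      stop("missing band: the aglycone 1204 cm^-1 ",
                           "denominator band was not found", call. = FALSE)
                    })
  a1215 <- areal_intensity_at(fit_bend, 1215, tol = 5)
  if (a898 <= 0) stop("missing band: zero area at 898 cm^-1", call. = FALSE)
  if (a1204 <= 0) stop("missing band: zero area at 1204 cm^-1", call. = FALSE)

  co <- fit_co$bands
  co <- co[co$center >= 1690 & co$center <= 1760 & co$area > 0, , drop = FALSE]
  co_main <- co[co$center < linked_cutoff, , drop = FALSE]
  if (!nrow(co_main) || sum(co_main$area) <= 0) {
    stop("missing band: no carbonyl sub-band below the linked-carbonyl ",
         "cutoff in 1690-1760 cm^-1", call. = FALSE)
  }
  nu_co <- sum(co_main$center * co_main$area) / sum(co_main$area)

  structure(list(nu_co = nu_co, r1 = a887 / a898,
                 r2 = (a1192 + a1215) / a1204,
                 window_fits = list(glucose = fit_glu, bending = fit_bend,
                                    carbonyl = fit_co),
                 linked_cutoff = linked_cutoff),
            class = "raman_parameters")
}

# Carbonyl fit with backward elimination. The five class centers are only
# 5-13 cm^-1 apart, so seeding them all can split one true band into
# redundant satellites (pseudo-Voigt decompositions are not unique).
# Remedy: fit the full seed set, then repeatedly drop the smallest-area
# sub-band and refit; the drop is kept while the refit residual stays at
# the noise floor (a redundant satellite costs nothing to remove, a real
# band does).
fit_carbonyl_window <- function(s, seeds, window = c(1640, 1780)) {
  refit <- function(sds) {
    fit_bands(s, window, sds, center_tol = seed_center_tol(sds, cap = 6),
              fwhm_bounds = c(4, 30))
  }
  fit <- refit(seeds)
  ymax <- max(abs(fit$data$intensity))
  floor_rms <- 1e-3 * ymax
  while (length(seeds) > 1) {
    i_small <- which.min(fit$bands$area)
    # seed nearest to the weakest fitted band
    drop_seed <- which.min(abs(seeds - fit$bands$center[i_small]))
    trial <- refit(seeds[-drop_seed])
    if (trial$residual_rms <= max(1.5 * fit$residual_rms, floor_rms)) {
      seeds <- seeds[-drop_seed]
      fit <- trial
    } else {
      break
    }
  }
  fit
}

#' @export
print.raman_parameters <- function(x, ...) {
  cat("Raman QC parameters:\n")
  cat(sprintf("  nu_CO = %.2f cm^-1 (area-weighted, linked class excluded)\n",
              x$nu_co))
  cat(sprintf("  R1 = I887/I898          = %.3f\n", x$r1))
  cat(sprintf("  R2 = (I1192+I1215)/I1204 = %.3f\n", x$r2))
  invisible(x)
}

#' Construct a ring estimate
#'
#' Bundles the inverted ring counts for one product. `n13` is defined as
#' `ntot_r1 - n19` (the R1-based total is the canonical one) and the
#' C13/C19 ratio as `n13 / n19`, reported only when `n19 > 0.05`.
#'
#' @param n19 Continuous rings on the C19 side.
#' @param ntot_r1,ntot_r2 Continuous total rings from the R1 and R2
#'   calibrations (`ntot_r2` may be `NA` if unavailable).
#' @param flags Character vector of out-of-range/extrapolation markers.
#' @return An object of class `ring_estimate` with fields `n19`, `ntot_r1`,
#'   `ntot_r2`, `n13`, `ratio_c13_c19`, `flags`.
#' @export
ring_estimate <- function(n19, ntot_r1, ntot_r2 = NA_real_,
                          flags = character(0)) {
  n13 <- ntot_r1 - n19
  ratio <- if (is.finite(n19) && n19 > 0.05) n13 / n19 else NA_real_
  if (is.na(ratio)) flags <- union(flags, "ratio_undefined")
  structure(list(n19 = n19, ntot_r1 = ntot_r1, ntot_r2 = ntot_r2,
                 n13 = n13, ratio_c13_c19 = ratio, flags = flags),
            class = "ring_estimate")
}

#' @export
print.ring_estimate <- function(x, ...) {
  cat(sprintf(
    "Ring estimate: C19 %.2f, total (R1) %.2f, total (R2) %s, C13 %.2f, C13/C19 %s\n",
    x$n19, x$ntot_r1,
    if (is.na(x$ntot_r2)) "NA" else sprintf("%.2f", x$ntot_r2),
    x$n13,
    if (is.na(x$ratio_c13_c19)) "undefined" else sprintf("%.2f", x$ratio_c13_c19)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Invert the calibrations into ring counts
#'
#' @param p A `raman_parameters` object.
#' @param cal_nu,cal_r1,cal_r2 Monotone `raman_calibration` models for
#'   nu_CO vs C19 rings and R1/R2 vs total rings (e.g. from
#'   [calibrate_reference()]).
#' @return A [ring_estimate]; out-of-range and extrapolation flags from the
#'   inversions are propagated.
#' @export
estimate_rings <- function(p, cal_nu, cal_r1, cal_r2) {
  stopifnot(inherits(p, "raman_parameters"))
  n19 <- invert(cal_nu, p$nu_co)
  nt1 <- invert(cal_r1, p$r1)
  nt2 <- invert(cal_r2, p$r2)
  flags <- character(0)
  if (isTRUE(attr(n19, "out_of_range")[1])) flags <- c(flags, "nu_co_out_of_range")
  if (isTRUE(attr(nt1, "out_of_range")[1])) flags <- c(flags, "r1_out_of_range")
  if (isTRUE(attr(nt2, "out_of_range")[1])) flags <- c(flags, "r2_out_of_range")
  ring_estimate(as.numeric(n19), as.numeric(nt1), as.numeric(nt2), flags)
}

#' Carbonyl class composition of a fitted carbonyl window
#'
#' Expresses each fitted carbonyl sub-band's area as a fraction of the
#' total carbonyl area and assigns it to the nearest carbonyl class (0-, 1-,
#' 2-, 3-ring or linked). Because the class centers track specific
#' glycoside structures, these fractions reflect semi-quantitatively the
#' blend composition.
#'
#' @param fit A converged `band_fit` covering the carbonyl region.
#' @param window Carbonyl window (default 1690-1760 cm^-1).
#' @return A data.frame with columns `class`, `center`, `area`, `fraction`
#'   (fractions sum to 1).
#' @export
carbonyl_composition <- function(fit, window = c(1690, 1760)) {
  stopifnot(inherits(fit, "band_fit"))
  b <- fit$bands
  b <- b[b$center >= window[1] & b$center <= window[2], , drop = FALSE]
  if (!nrow(b) || sum(b$area) <= 0) {
    stop("carbonyl window has no fitted sub-bands with positive area",
         call. = FALSE)
  }
  cls <- carbonyl_classes()
  idx <- vapply(b$center, function(cc) which.min(abs(cls$center - cc)),
                integer(1))
  out <- data.frame(class = cls$class[idx], center = b$center,
                    area = b$area, fraction = b$area / sum(b$area))
  out[order(out$center), ]
}

#' Flag an extraneous band near 869 cm^-1
#'
#' Screens the glucose-window fit for an unassigned band at ~869 cm^-1 —
#' extraneous to every steviol diterpene vibration and tentatively
#' attributed to an added artificial sweetener (an assignment that needs
#' independent confirmation). The flag is raised when a significant
#' residual peak refits to a band with center within `869 +/- 5` cm^-1 and
#' area of at least 1% of the window's total fitted area, and that band is
#' not claimed by any steviol assignment.
#'
#' @param s The preprocessed [raman_spectrum] the fit came from.
#' @param fit The `band_fit` over 850-950 cm^-1 with steviol seeds only.
#' @param target Extraneous marker center (default 869 cm^-1).
#' @param tol Center tolerance (default 5 cm^-1).
#' @param min_frac Minimum area fraction of the window total (default 1%).
#' @return A list: `flag` (logical), `center`, `relative_area`, `note`.
#' @export
detect_extraneous_band <- function(s, fit, target = 869, tol = 5,
                                   min_frac = 0.01) {
  stopifnot(inherits(fit, "band_fit"))
  note <- paste("assignment of the ~869 cm^-1 band to an artificial",
                "sweetener is tentative and needs additional confirmation")
  res <- residuals(fit)
  nu <- fit$data$wavenumber
  ymax <- max(abs(fit$data$intensity))
  sig <- stats::mad(res)
  peak_i <- which.max(res)
  peak_h <- res[peak_i]
  if (peak_h < max(5 * sig, 0.001 * ymax)) {
    return(list(flag = FALSE, center = NA_real_, relative_area = 0,
                note = note))
  }
  # refit with an extra seed at the residual peak
  seeds <- c(fit$seeds$center, nu[peak_i])
  refit <- fit_bands(s, fit$window, seeds,
                     center_tol = seed_center_tol(seeds))
  extra <- refit$bands
  assigned <- fit$seeds$center
  unclaimed <- vapply(extra$center, function(cc) {
    all(abs(cc - assigned) > tol)
  }, logical(1))
  cand <- extra[unclaimed & abs(extra$center - target) <= tol, , drop = FALSE]
  tot <- sum(refit$bands$area)
  if (nrow(cand) && tot > 0) {
    cand <- cand[which.max(cand$area), ]
    frac <- cand$area / tot
    if (frac >= min_frac) {
      return(list(flag = TRUE, center = cand$center, relative_area = frac,
                  note = note))
    }
  }
  list(flag = FALSE, center = NA_real_, relative_area = 0, note = note)
}

#' Comparative taste classification of a product batch
#'
#' Assigns within-batch comparative taste labels from the structure->taste
#' rules for steviol glycosides: more total rings means stronger sweetness;
#' a lower C13/C19 ring ratio means a faster sweetness peak; fewer C19-side
#' rings mean longer-lingering bitterness. Because the published product
#' gradings coordinate all three labels per product, the batch is first
#' partitioned into quality groups by gap-clustering the R1-based total
#' ring count (groups split where consecutive sorted totals differ by more
#' than `gap`), and each group receives a coordinated label triple; ties
#' share labels. Labels are strictly comparative superlatives — an absolute
#' sweetness scale is deliberately not invented.
#'
#' @param batch A named list of [ring_estimate] objects (>= 2 products), or
#'   a data.frame with columns `product`, `n19`, `ntot_r1` (and optionally
#'   `ratio_c13_c19`).
#' @param gap Ring-count gap that separates quality groups (default 0.2).
#' @return A data.frame: `product`, `sweetness`, `sweet_perception`,
#'   `bitter_perception`, `group` (1 = best).
#' @export
classify_taste <- function(batch, gap = 0.2) {
  if (is.data.frame(batch)) {
    df <- batch
    stopifnot(all(c("product", "n19", "ntot_r1") %in% names(df)))
  } else {
    stopifnot(is.list(batch), length(batch) >= 1,
              all(vapply(batch, inherits, logical(1), "ring_estimate")))
    df <- data.frame(
      product = if (!is.null(names(batch))) names(batch)
                else paste0("product", seq_along(batch)),
      n19 = vapply(batch, `[[`, numeric(1), "n19"),
      ntot_r1 = vapply(batch, `[[`, numeric(1), "ntot_r1"))
  }
  if (nrow(df) < 2) {
    stop("comparative labels are undefined for a batch of ", nrow(df),
         "; provide at least 2 products", call. = FALSE)
  }
  o <- order(-df$ntot_r1)
  sorted <- df$ntot_r1[o]
  grp_sorted <- cumsum(c(1, as.integer(-diff(sorted) > gap)))
  grp <- integer(nrow(df)); grp[o] <- grp_sorted
  k <- max(grp)
  level <- function(g) {
    if (k == 1) 1L else if (g == 1) 1L else if (g == k) 3L else 2L
  }
  lev <- vapply(grp, level, integer(1))
  sweet_lab <- c("highest", "intermediate", "lowest")
  speed_lab <- c("fastest", "slow", "slowest")
  bitter_lab <- c("shortest", "long", "longest")
  data.frame(product = df$product,
             sweetness = sweet_lab[lev],
             sweet_perception = speed_lab[lev],
             bitter_perception = bitter_lab[lev],
             group = grp)
}

#' Run the full QC pipeline on one or more products
#'
#' For each product: average replicates -> subtract baseline -> normalize
#' -> fit the three windows -> compute nu_CO, R1, R2 -> invert the
#' calibrations into ring counts -> carbonyl class composition ->
#' extraneous-band flag; finally (batches of >= 2) comparative taste
#' labels. A failing product is carried in the result as a structured
#' failure and the batch continues. The pipeline is deterministic end to
#' end.
#'
#' @param spectra Named list, one element per product. Each element is a
#'   [raman_spectrum], a character vector of spectrum file paths
#'   (replicates), or a list of spectra.
#' @param calibration A list with `nu_co`, `r1`, `r2` calibration models
#'   (e.g. from [calibrate_reference()] or [read_calibration()]).
#' @param config A [preprocess_config].
#' @return An object of class `qc_batch`: a list with `reports` (one
#'   `qc_report` per successful product), `failures` (named list of error
#'   messages) and `taste` (label data.frame, when >= 2 products
#'   succeeded).
#' @export
run_qc <- function(spectra, calibration, config = preprocess_config()) {
  stopifnot(is.list(spectra), length(spectra) >= 1)
  if (is.null(names(spectra)) || any(!nzchar(names(spectra)))) {
    names(spectra) <- paste0("product", seq_along(spectra))
  }
  stopifnot(all(c("nu_co", "r1", "r2") %in% names(calibration)))
  reports <- list(); failures <- list()
  for (nm in names(spectra)) {
    rep_result <- tryCatch({
      reps <- spectra[[nm]]
      if (inherits(reps, "raman_spectrum")) reps <- list(reps)
      if (is.character(reps)) reps <- lapply(reps, read_spectrum)
      avg <- average_replicates(reps)
      pre <- preprocess(avg, config)
      p <- compute_parameters(pre)
      est <- estimate_rings(p, calibration$nu_co, calibration$r1,
                            calibration$r2)
      comp <- carbonyl_composition(p$window_fits$carbonyl)
      adu <- detect_extraneous_band(pre, p$window_fits$glucose)
      structure(list(product = nm, parameters = p, rings = est,
                     carbonyl_composition = comp, adulterant = adu,
                     config = unclass(config),
                     calibration_provenance = lapply(
                       calibration[c("nu_co", "r1", "r2")],
                       function(m) list(parameter = m$parameter,
                                        form = m$form,
                                        fit_rms = m$fit_rms))),
                class = "qc_report")
    }, error = function(e) e)
    if (inherits(rep_result, "error")) {
      failures[[nm]] <- conditionMessage(rep_result)
    } else {
      reports[[nm]] <- rep_result
    }
  }
  taste <- NULL
  if (length(reports) >= 2) {
    taste <- classify_taste(lapply(reports, `[[`, "rings"))
    for (nm in names(reports)) {
      reports[[nm]]$taste <- taste[taste$product == nm,
                                   c("sweetness", "sweet_perception",
                                     "bitter_perception")]
    }
  }
  structure(list(reports = reports, failures = failures, taste = taste),
            class = "qc_batch")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$product, "\n")
  print(x$parameters)
  print(x$rings)
  cat("  carbonyl composition:\n")
  comp <- x$carbonyl_composition
  for (i in seq_len(nrow(comp))) {
    cat(sprintf("    %-7s %.1f cm^-1  %.1f%%\n", comp$class[i],
                comp$center[i], 100 * comp$fraction[i]))
  }
  if (isTRUE(x$adulterant$flag)) {
    cat(sprintf("  ADULTERANT FLAG: band at %.1f cm^-1 (%.1f%% of window area)\n",
                x$adulterant$center, 100 * x$adulterant$relative_area))
    cat("   ", x$adulterant$note, "\n")
  } else {
    cat("  no extraneous ~869 cm^-1 band detected\n")
  }
  if (!is.null(x$taste)) {
    cat(sprintf("  taste: %s sweetness, %s sweet perception, %s bitter perception\n",
                x$taste$sweetness, x$taste$sweet_perception,
                x$taste$bitter_perception))
  }
  invisible(x)
}

#' @export
print.qc_batch <- function(x, ...) {
  cat(sprintf("QC batch: %d product(s), %d failure(s)\n\n",
              length(x$reports), length(x$failures)))
  print(summary(x))
  for (nm in names(x$failures)) {
    cat(sprintf("FAILED %s: %s\n", nm, x$failures[[nm]]))
  }
  invisible(x)
}

#' Flat per-product summary of a QC batch
#'
#' One row per product with the published-table layout: rings on C19,
#' totals by both calibrations, C13/C19 ratio, adulterant flag and taste
#' labels. Values are printed at 2 decimals by the print method but kept at
#' full precision here.
#'
#' @param object A `qc_batch`.
#' @param ... Unused.
#' @return A data.frame.
#' @export
summary.qc_batch <- function(object, ...) {
  if (!length(object$reports)) return(data.frame())
  rows <- lapply(object$reports, function(r) {
    data.frame(
      product = r$product,
      nu_co = r$parameters$nu_co, r1 = r$parameters$r1, r2 = r$parameters$r2,
      rings_c19 = r$rings$n19, total_rings_1 = r$rings$ntot_r1,
      total_rings_2 = r$rings$ntot_r2, rings_c13 = r$rings$n13,
      ratio_c13_c19 = r$rings$ratio_c13_c19,
      adulterant = isTRUE(r$adulterant$flag),
      sweetness = if (!is.null(r$taste)) r$taste$sweetness else NA_character_,
      sweet_perception = if (!is.null(r$taste)) r$taste$sweet_perception else NA_character_,
      bitter_perception = if (!is.null(r$taste)) r$taste$bitter_perception else NA_character_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a QC batch to disk
#'
#' Writes the full report as JSON and, optionally, the flat per-product
#' summary as CSV.
#'
#' @param batch A `qc_batch`.
#' @param json_path Output JSON path.
#' @param csv_path Optional output CSV path for the flat summary.
#' @return `json_path`, invisibly.
#' @export
write_qc_report <- function(batch, json_path, csv_path = NULL) {
  stopifnot(inherits(batch, "qc_batch"))
  strip_report <- function(r) {
    list(product = r$product,
         parameters = list(nu_co = r$parameters$nu_co, r1 = r$parameters$r1,
                           r2 = r$parameters$r2),
         rings = unclass(r$rings),
         carbonyl_composition = r$carbonyl_composition,
         adulterant = r$adulterant,
         taste = r$taste,
         config = r$config,
         calibration = r$calibration_provenance)
  }
  obj <- list(reports = lapply(unname(batch$reports), strip_report),
              failures = batch$failures)
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  if (!is.null(csv_path)) {
    utils::write.csv(summary(batch), csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
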