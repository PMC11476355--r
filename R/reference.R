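# Reference tables are shipped as versioned CSV resources under extdata and
# cached per session.
.ref_cache <- new.env(parent = emptyenv())

read_ref_csv <- function(file) {
  if (!is.null(.ref_cache[[file]])) return(.ref_cache[[file]])
  path <- system.file("extdata", file, package = "steviaQC")
  if (!nzchar(path)) {
    # allow use from a source checkout (devtools::load_all)
    path <- file.path("inst", "extdata", file)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .ref_cache[[file]] <- df
  df
}

#' The elementary diterpene glycoside library
#'
#' The twelve elementary steviol glycosides with their Hill-notation
#' formulas, molecular weights (g/mol), and glucose-ring counts on the C19
#' (carboxyl ester) and C13 (tertiary alcohol) sides of the aglycone.
#' `r1_ref`/`r2_ref` are the synthetic reference intensity ratios used by
#' the spectrum generator: linear in the total ring count with small
#' per-compound structural offsets (the measured per-compound ratios are
#' not published as numbers, so these are generator conventions, not
#' instrument values).
#'
#' @return A data.frame with one row per compound and columns `name`,
#'   `formula`, `mw`, `rings_c19`, `rings_c13`, `rings_total`, `r1_ref`,
#'   `r2_ref`, `has_linked_carbonyl`, `note`.
#' @export
stevia_compounds <- function() {
  df <- read_ref_csv("stevia_compounds.csv")
  df$rings_total <- df$rings_c19 + df$rings_c13
  df
}

#' Look up one elementary glycoside record
#'
#' Case-insensitive; "Rebaudioside X" is accepted as an alias for
#' Rebaudioside M.
#'
#' @param name Compound name.
#' @return A one-row data.frame (see [stevia_compounds()]).
#' @export
get_compound <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  lib <- stevia_compounds()
  key <- tolower(trimws(name))
  if (key == "rebaudioside x") key <- "rebaudioside m"
  hit <- which(tolower(lib$name) == key)
  if (!length(hit)) {
    stop("unknown compound '", name, "'; valid names: ",
         paste(lib$name, collapse = ", "), call. = FALSE)
  }
  lib[hit, , drop = FALSE]
}

#' Molecular weight from an elemental formula
#'
#' Conventional atomic weights (C 12.0107, H 1.00794, O 15.9994) are used;
#' they reproduce the library's printed molecular weights to better than
#' 0.02 g/mol. Full precision is kept internally; round only at report
#' time.
#'
#' @param formula Hill-notation formula restricted to C, H and O, e.g.
#'   `"C44H70O23"`.
#' @return Molecular weight in g/mol.
#' @examples
#' mw_from_formula("C44H70O23")  # Rebaudioside A, 967.01
#' @export
mw_from_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  f <- gsub("[_ ]", "", formula)
  weights <- c(C = 12.0107, H = 1.00794, O = 15.9994)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f, perl = TRUE)[[1]]
  toks <- regmatches(f, list(m))[[1]]
  if (!length(toks) || paste(toks, collapse = "") != f) {
    stop("malformed formula: '", formula, "'", call. = FALSE)
  }
  total <- 0
  for (tok in toks) {
    el <- gsub("[0-9]", "", tok)
    n <- gsub("[^0-9]", "", tok)
    n <- if (nzchar(n)) as.numeric(n) else 1
    if (!el %in% names(weights)) {
      stop("unknown element '", el, "' in formula '", formula,
           "' (only C, H, O are supported)", call. = FALSE)
    }
    if (n <= 0) stop("element counts must be positive in '", formula, "'",
                     call. = FALSE)
    total <- total + n * weights[[el]]
  }
  total
}

#' Band assignment table
#'
#' The band assignments used to seed window fits: glucose-ring modes (C-O
#' and C-C stretching at 850-950 cm^-1; C-C-H and C-O-H bending at
#' 1150-1250 cm^-1), aglycone-core modes (740, 898, 1004-1075, 1204, 1670,
#' ~1738 cm^-1), the linked-carbonyl class and the ~869 cm^-1 extraneous
#' (suspected artificial-sweetener) marker.
#'
#' @param moiety Optional filter: one of `"glucose_ring"`,
#'   `"aglycone_core"`, `"linked_carbonyl"`, `"extraneous"`.
#' @return A data.frame with columns `label`, `moiety`, `center`,
#'   `window_lo`, `window_hi`, in stable (table) order.
#' @export
list_assignments <- function(moiety = NULL) {
  df <- read_ref_csv("band_assignments.csv")
  if (!is.null(moiety)) {
    moiety <- match.arg(moiety, c("glucose_ring", "aglycone_core",
                                  "linked_carbonyl", "extraneous"))
    df <- df[df$moiety == moiety, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Carbonyl class centers
#'
#' Generator/classification anchors for the C19=O stretching wavenumber as
#' a function of the number of glucose rings on the C19 side, plus the
#' linked-carbonyl class (~1738 cm^-1, attributed to a modified C16/C17
#' site rather than to C19 glycosylation). The 0-ring (1706 cm^-1) and
#' 1-ring (1719 cm^-1) anchors and the linked class are printed values; the
#' 2- and 3-ring centers are interpolations kept in this single table so
#' they can be re-anchored against a calibrated instrument.
#'
#' @return A data.frame with columns `class`, `rings_c19` (NA for the
#'   linked class), `center`, `provenance`.
#' @export
carbonyl_classes <- function() {
  read_ref_csv("carbonyl_classes.csv")
}

#' Published ring estimates for five commercial stevia products
#'
#' The Raman-derived ring-count estimates for the five commercial products
#' (Morita 1, Morita 2, China 1, China 2, Fermented): rings on the C19
#' side, and total rings by the R1-based and R2-based calibrations. These
#' are the worked-example inputs for the C13/C19 ratio arithmetic and the
#' comparative taste classifier.
#'
#' @return A data.frame with columns `product`, `rings_c19`,
#'   `total_rings_1`, `total_rings_2`.
#' @export
stevia_products <- function() {
  read_ref_csv("stevia_products.csv")
}
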