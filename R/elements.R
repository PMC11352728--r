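# Element reference data: covalent radii (for bond perception) and van der
# Waals radii (for steric descriptors), shipped as plain CSV under extdata.

the <- new.env(parent = emptyenv())

#' Element radii reference table
#'
#' Covalent radii used for bond perception and van der Waals radii used for
#' all steric descriptors (percent buried volume, cone angle, sterimol).
#' Values are the widely used single-bond covalent radii and the classic
#' van der Waals compilation extended with transition-metal entries.
#'
#' @return A tibble with columns `element`, `atomic_number`, `r_cov` and
#'   `r_vdw` (both in Angstrom).
#' @export
#' @examples
#' element_radii()
element_radii <- function() {
  if (is.null(the$radii)) {
    path <- system.file("extdata", "element_radii.csv", package = "chiralcat",
                        mustWork = TRUE)
    the$radii <- readr::read_csv(path, show_col_types = FALSE,
                                 progress = FALSE)
  }
  the$radii
}

# Look up a per-element column for a vector of symbols; errors name the
# offending element so malformed inputs fail loudly.
lookup_element <- function(elements, column) {
  tab <- element_radii()
  idx <- match(elements, tab$element)
  if (anyNA(idx)) {
    bad <- unique(elements[is.na(idx)])
    stop("element(s) not in the bundled radii table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tab[[column]][idx]
}

covalent_radius <- function(elements) lookup_element(elements, "r_cov")
vdw_radius      <- function(elements) lookup_element(elements, "r_vdw")
atomic_number   <- function(elements) lookup_element(elements, "atomic_number")
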