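# Electronic sidecars: per-structure JSON files carrying the quantities that
# come out of an electronic-structure calculation (HOMO-LUMO gap, NBO
# charges, donor lone-pair occupancies).  The package ingests these values;
# it never runs quantum chemistry itself.

SIDECAR_CONTEXTS <- c("complex", "free_ligand")

#' Create an electronic sidecar
#'
#' @param structure_id Id of the paired [xyz_structure()].
#' @param context Either `"complex"` (values computed on the full
#'   `[Rh(L)(NBD)]+` cation) or `"free_ligand"` (single point on the ligand
#'   geometry extracted from the complex).
#' @param homo_lumo_gap HOMO-LUMO gap in eV (required).
#' @param nbo_charge Named numeric vector of NBO partial charges (e); names
#'   are 1-based atom indices in the paired structure.
#' @param lone_pair_occupancy Named numeric vector of donor lone-pair
#'   occupancies (electrons, each in \[0, 2\]); names as above.
#'
#' @return An `electronic_sidecar` object.
#' @export
electronic_sidecar <- function(structure_id, context, homo_lumo_gap,
                               nbo_charge = numeric(),
                               lone_pair_occupancy = numeric()) {
  if (!context %in% SIDECAR_CONTEXTS) {
    stop("sidecar context must be one of: ",
         paste(SIDECAR_CONTEXTS, collapse = ", "), call. = FALSE)
  }
  if (length(homo_lumo_gap) != 1 || !is.finite(homo_lumo_gap)) {
    stop("homo_lumo_gap must be a single finite value (eV)", call. = FALSE)
  }
  nbo_charge <- as_atom_map(nbo_charge, "nbo_charge")
  lone_pair_occupancy <- as_atom_map(lone_pair_occupancy,
                                     "lone_pair_occupancy")
  if (length(lone_pair_occupancy) &&
      any(lone_pair_occupancy < 0 | lone_pair_occupancy > 2)) {
    stop("lone-pair occupancies must lie in [0, 2]", call. = FALSE)
  }
  structure(
    list(
      structure_id = as.character(structure_id),
      context = context,
      homo_lumo_gap = as.numeric(homo_lumo_gap),
      nbo_charge = nbo_charge,
      lone_pair_occupancy = lone_pair_occupancy
    ),
    class = "electronic_sidecar"
  )
}

as_atom_map <- function(x, what) {
  if (!length(x)) return(stats::setNames(numeric(), character()))
  if (is.null(names(x)) || any(names(x) == "")) {
    stop(what, " must be a named vector keyed by atom index", call. = FALSE)
  }
  idx <- suppressWarnings(as.integer(names(x)))
  if (anyNA(idx) || any(idx < 1)) {
    stop(what, " keys must be positive (1-based) atom indices", call. = FALSE)
  }
  stats::setNames(as.numeric(x), as.character(idx))
}

#' @export
print.electronic_sidecar <- function(x, ...) {
  cat(sprintf(
    "<electronic_sidecar '%s' (%s): gap %.3f eV, %d charges, %d occupancies>\n",
    x$structure_id, x$context, x$homo_lumo_gap,
    length(x$nbo_charge), length(x$lone_pair_occupancy)
  ))
  invisible(x)
}

#' Read an electronic sidecar from JSON
#'
#' @param path Path to a JSON file with fields `structure_id`, `context`,
#'   `homo_lumo_gap` and optional `nbo_charge` / `lone_pair_occupancy`
#'   objects keyed by 1-based atom index.
#' @param structure Optional paired [xyz_structure()]; when given, every
#'   referenced atom index is checked to exist.
#' @return An [electronic_sidecar()].
#' @export
read_sidecar <- function(path, structure = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("structure_id", "context", "homo_lumo_gap")) {
    if (is.null(raw[[field]])) {
      stop("sidecar is missing required field '", field, "'", call. = FALSE)
    }
  }
  sc <- electronic_sidecar(
    structure_id = raw$structure_id,
    context = raw$context,
    homo_lumo_gap = raw$homo_lumo_gap,
    nbo_charge = unlist(raw$nbo_charge %||% numeric()),
    lone_pair_occupancy = unlist(raw$lone_pair_occupancy %||% numeric())
  )
  if (!is.null(structure)) validate_sidecar_indices(sc, structure)
  sc
}

#' Write an electronic sidecar to JSON
#'
#' @param sidecar An [electronic_sidecar()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(sidecar, path) {
  jsonlite::write_json(
    list(
      structure_id = sidecar$structure_id,
      context = sidecar$context,
      homo_lumo_gap = sidecar$homo_lumo_gap,
      nbo_charge = as.list(sidecar$nbo_charge),
      lone_pair_occupancy = as.list(sidecar$lone_pair_occupancy)
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

validate_sidecar_indices <- function(sidecar, structure) {
  n <- n_atoms(structure)
  idx <- as.integer(c(names(sidecar$nbo_charge),
                      names(sidecar$lone_pair_occupancy)))
  if (length(idx) && any(idx > n)) {
    stop(sprintf(
      "sidecar '%s' references atom index %d but the structure has %d atoms",
      sidecar$structure_id, max(idx), n
    ), call. = FALSE)
  }
  invisible(sidecar)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
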