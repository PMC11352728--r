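# Atomic structures and XYZ input/output.
#
# A structure is a light S3 wrapper around an atom tibble so that geometry
# code can stay vectorised while user-facing functions keep a tabular
# surface.  Atom indices are 1-based everywhere in the package, including
# electronic sidecars.

#' Create an atomic structure
#'
#' @param elements Character vector of element symbols.
#' @param coords Numeric matrix (n x 3) of Cartesian coordinates in Angstrom,
#'   or a data frame with columns `x`, `y`, `z`.
#' @param id Structure identifier.
#' @param charge Total charge of the species (integer; +1 for the cationic
#'   rhodium precatalysts).
#'
#' @return An object of class `xyz_structure`: a list with `id`, `charge`
#'   and an `atoms` tibble (`element`, `x`, `y`, `z`).
#' @export
#' @examples
#' xyz_structure("H2", c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
xyz_structure <- function(id, elements, coords, charge = 0L) {
  if (is.data.frame(coords)) coords <- as.matrix(coords[, c("x", "y", "z")])
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(elements) != nrow(coords)) {
    stop("`elements` and `coords` disagree on the atom count", call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  lookup_element(elements, "element") # validates the symbols
  structure(
    list(
      id = as.character(id),
      charge = as.integer(charge),
      atoms = tibble::tibble(
        element = as.character(elements),
        x = coords[, 1], y = coords[, 2], z = coords[, 3]
      )
    ),
    class = "xyz_structure"
  )
}

#' @export
print.xyz_structure <- function(x, ...) {
  cat(sprintf("<xyz_structure '%s': %d atoms, charge %+d>\n",
              x$id, n_atoms(x), x$charge))
  print(x$atoms, n = 6)
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure An `xyz_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Coordinates of a structure as a matrix
#' @param structure An `xyz_structure`.
#' @return An n x 3 numeric matrix (Angstrom).
#' @export
coords_matrix <- function(structure) {
  cbind(structure$atoms$x, structure$atoms$y, structure$atoms$z)
}

#' Read an XYZ file
#'
#' Standard XYZ dialect: first line is the atom count, second line is a free
#' comment that may carry a `charge=<int>` token, then one `El x y z` line
#' per atom.  Parse failures report the offending line number.
#'
#' @param path Path to the XYZ file.
#' @param id Structure id; defaults to the file name without extension.
#' @return An [xyz_structure()].
#' @export
read_xyz <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) {
    stop("XYZ parse error at line 1: file too short", call. = FALSE)
  }
  n <- suppressWarnings(as.integer(trimws(lines[[1]])))
  if (is.na(n) || n < 1) {
    stop("XYZ parse error at line 1: malformed atom count", call. = FALSE)
  }
  if (length(lines) < 2 + n) {
    stop(sprintf(
      "XYZ parse error at line %d: expected %d atom lines, found %d",
      length(lines) + 1, n, length(lines) - 2
    ), call. = FALSE)
  }
  charge <- 0L
  m <- regmatches(lines[[2]], regexec("charge=(-?[0-9]+)", lines[[2]]))[[1]]
  if (length(m) == 2) charge <- as.integer(m[[2]])

  elements <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    ln <- 2 + k
    tok <- strsplit(trimws(lines[[ln]]), "\\s+")[[1]]
    if (length(tok) < 4) {
      stop(sprintf("XYZ parse error at line %d: expected 'El x y z'", ln),
           call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz)) {
      stop(sprintf("XYZ parse error at line %d: non-numeric coordinate", ln),
           call. = FALSE)
    }
    elements[k] <- tok[[1]]
    coords[k, ] <- xyz
  }
  tab <- element_radii()
  bad <- which(!(elements %in% tab$element))
  if (length(bad)) {
    stop(sprintf("XYZ parse error at line %d: unknown element '%s'",
                 2 + bad[[1]], elements[bad[[1]]]), call. = FALSE)
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  xyz_structure(id, elements, coords, charge)
}

#' Write an XYZ file
#'
#' Inverse of [read_xyz()]; coordinates are written with 8 decimals so a
#' read/write round trip preserves them to well below 1e-6 Angstrom.  The
#' total charge is stored as a `charge=<int>` token on the comment line.
#'
#' @param structure An [xyz_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structure, path) {
  at <- structure$atoms
  lines <- c(
    sprintf("%d", nrow(at)),
    sprintf("%s charge=%d", structure$id, structure$charge),
    sprintf("%-2s %14.8f %14.8f %14.8f", at$element, at$x, at$y, at$z)
  )
  writeLines(lines, path)
  invisible(path)
}

# Reflect a structure through the xy-plane (z -> -z): produces the mirror
# image (enantiomer) of a chiral arrangement.
reflect_structure <- function(structure) {
  structure$atoms$z <- -structure$atoms$z
  structure$id <- paste0(structure$id, "_mirror")
  structure
}

# Apply a rigid rotation (3x3 orthonormal matrix) about the origin.
rotate_structure <- function(structure, rotation) {
  xyz <- coords_matrix(structure) %*% t(rotation)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}
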