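# The fixed 34-descriptor catalyst schema: 15 steric (S1-S15), 8 geometric
# (G1-G8) and 11 electronic (E1-E11) descriptors per [Rh(L)(NBD)]+
# precatalyst.  The schema is frozen here as a registry so feature matrices
# are reproducible; anchored members are S15 (buried volume centred on the
# min donor), G4 (metal-min donor distance), E5 (metal NBO charge), E7
# (free-ligand min-donor lone-pair occupancy) and E10 (free-ligand
# max-donor NBO charge).

#' The catalyst descriptor schema
#'
#' Registry of the 34 named catalyst descriptors in their canonical column
#' order.  Steric entries are ligand-only percent buried volumes over a
#' centre x probe-radius design (metal / donor midpoint / max donor at 3.5,
#' 4.5 and 6.0 Angstrom, four metal-centred quadrants at 3.5, one
#' hydrogen-excluded metal value, and the min-donor 3.5 value as S15);
#' geometric entries are the bite angle, exact cone angle, diene dihedral
#' and the five framework distances; electronic entries are the gap, donor
#' NBO charges and lone-pair occupancies and the metal NBO charge, for both
#' the complex and the free ligand.
#'
#' @return Tibble with columns `name`, `category` (`steric` / `geometric` /
#'   `electronic`) and `description`, in canonical column order.
#' @export
#' @examples
#' dplyr::count(catalyst_schema(), category)
catalyst_schema <- function() {
  tibble::tribble(
    ~name, ~category, ~description,
    "S1",  "steric", "quadrant x+y+ %Vbur, metal centre, r = 3.5 A",
    "S2",  "steric", "quadrant x-y+ %Vbur, metal centre, r = 3.5 A",
    "S3",  "steric", "quadrant x+y- %Vbur, metal centre, r = 3.5 A",
    "S4",  "steric", "quadrant x-y- %Vbur, metal centre, r = 3.5 A",
    "S5",  "steric", "%Vbur, metal centre, r = 3.5 A",
    "S6",  "steric", "%Vbur, metal centre, r = 3.5 A, hydrogens excluded",
    "S7",  "steric", "%Vbur, metal centre, r = 4.5 A",
    "S8",  "steric", "%Vbur, metal centre, r = 6.0 A",
    "S9",  "steric", "%Vbur, donor midpoint centre, r = 3.5 A",
    "S10", "steric", "%Vbur, donor midpoint centre, r = 4.5 A",
    "S11", "steric", "%Vbur, donor midpoint centre, r = 6.0 A",
    "S12", "steric", "%Vbur, max donor centre, r = 3.5 A",
    "S13", "steric", "%Vbur, max donor centre, r = 4.5 A",
    "S14", "steric", "%Vbur, max donor centre, r = 6.0 A",
    "S15", "steric", "%Vbur, min donor centre, r = 3.5 A",
    "G1",  "geometric", "bite angle donor-metal-donor (deg)",
    "G2",  "geometric", "exact cone angle of the ligand at the metal (deg)",
    "G3",  "geometric", "signed diene dihedral min donor-metal-mid1-mid2 (deg)",
    "G4",  "geometric", "distance metal - min donor (A)",
    "G5",  "geometric", "distance metal - max donor (A)",
    "G6",  "geometric", "distance min donor - max donor (A)",
    "G7",  "geometric", "distance metal - nearer olefin midpoint (A)",
    "G8",  "geometric", "distance metal - farther olefin midpoint (A)",
    "E1",  "electronic", "HOMO-LUMO gap of the complex (eV)",
    "E2",  "electronic", "NBO charge of the min donor, complex (e)",
    "E3",  "electronic", "NBO charge of the max donor, complex (e)",
    "E4",  "electronic", "lone-pair occupancy of the min donor, complex",
    "E5",  "electronic", "NBO charge of the metal centre (e)",
    "E6",  "electronic", "lone-pair occupancy of the max donor, complex",
    "E7",  "electronic", "lone-pair occupancy of the min donor, free ligand",
    "E8",  "electronic", "lone-pair occupancy of the max donor, free ligand",
    "E9",  "electronic", "NBO charge of the min donor, free ligand (e)",
    "E10", "electronic", "NBO charge of the max donor, free ligand (e)",
    "E11", "electronic", "HOMO-LUMO gap of the free ligand (eV)"
  )
}

sidecar_value <- function(sidecar, field, index, descriptor) {
  v <- sidecar[[field]][as.character(index)]
  if (is.null(v) || length(v) != 1 || is.na(v)) {
    stop(sprintf("descriptor %s failed: sidecar '%s' has no %s for atom %d",
                 descriptor, sidecar$structure_id, field, index),
         call. = FALSE)
  }
  unname(v)
}

with_descriptor <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("descriptor %s failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Featurize one precatalyst into the 34-descriptor vector
#'
#' Runs the full pipeline on one complex: bond perception, partition into
#' metal / ligand / auxiliary diene, charge-based donor labelling, free
#' ligand extraction, then every steric, geometric and electronic
#' descriptor of [catalyst_schema()].  Steric descriptors see the ligand
#' atoms only.  Any failing sub-descriptor aborts with the descriptor name;
#' values are never silently NaN.  Monodentate ligands fill both donor
#' roles with their single donor (flagged with a message).
#'
#' @param complex_structure [xyz_structure()] of the `[Rh(L)(NBD)]+` cation.
#' @param sidecar_complex Complex-context [electronic_sidecar()].
#' @param sidecar_free_ligand Free-ligand-context [electronic_sidecar()],
#'   keyed by free-ligand atom indices (the [extract_free_ligand()]
#'   numbering).
#' @param metal_symbol Metal element symbol (default "Rh").
#' @param grid_spacing Buried-volume voxel edge (default 0.05 Angstrom;
#'   see [steric_defaults()] for the other conventions).
#' @param ligand_id Identifier for the output row (defaults to the
#'   structure id).
#' @return One-row tibble: `ligand_id` followed by the 34 descriptor
#'   columns in schema order.
#' @export
featurize_catalyst <- function(complex_structure, sidecar_complex,
                               sidecar_free_ligand, metal_symbol = "Rh",
                               grid_spacing = 0.05, ligand_id = NULL) {
  if (sidecar_complex$context != "complex" ||
      sidecar_free_ligand$context != "free_ligand") {
    stop("sidecars must have contexts 'complex' and 'free_ligand'",
         call. = FALSE)
  }
  graph <- build_graph(complex_structure)
  part <- partition_complex(complex_structure, graph, metal_symbol)
  donors <- assign_donor_labels(part, sidecar_complex)
  if (donors$min_donor == donors$max_donor) {
    message("monodentate ligand: single donor fills both min/max roles")
  }
  free <- extract_free_ligand(complex_structure, part)
  imap <- attr(free, "index_map")
  to_free <- function(old) imap$new[match(old, imap$old)]

  metal <- part$metal_index
  lig <- part$ligand_atoms
  xyz <- coords_matrix(complex_structure)
  mid_donors <- (xyz[donors$min_donor, ] + xyz[donors$max_donor, ]) / 2

  vb <- function(center, r, ...) {
    buried_volume(complex_structure, lig, center, sphere_radius = r,
                  grid_spacing = grid_spacing, ...)
  }
  vals <- c()

  quad <- with_descriptor("S1-S4", quadrant_buried_volume(
    complex_structure, lig, metal, z_target = mid_donors,
    xz_atom = donors$max_donor, sphere_radius = 3.5,
    grid_spacing = grid_spacing
  ))
  vals[c("S1", "S2", "S3", "S4")] <- quad$vbur
  vals["S5"] <- with_descriptor("S5", vb(metal, 3.5))
  vals["S6"] <- with_descriptor("S6", vb(metal, 3.5,
                                         include_hydrogens = FALSE))
  vals["S7"] <- with_descriptor("S7", vb(metal, 4.5))
  vals["S8"] <- with_descriptor("S8", vb(metal, 6.0))
  vals["S9"] <- with_descriptor("S9", vb(mid_donors, 3.5))
  vals["S10"] <- with_descriptor("S10", vb(mid_donors, 4.5))
  vals["S11"] <- with_descriptor("S11", vb(mid_donors, 6.0))
  vals["S12"] <- with_descriptor("S12", vb(donors$max_donor, 3.5,
                                           excluded_atoms = donors$max_donor))
  vals["S13"] <- with_descriptor("S13", vb(donors$max_donor, 4.5,
                                           excluded_atoms = donors$max_donor))
  vals["S14"] <- with_descriptor("S14", vb(donors$max_donor, 6.0,
                                           excluded_atoms = donors$max_donor))
  vals["S15"] <- with_descriptor("S15", vb(donors$min_donor, 3.5,
                                           excluded_atoms = donors$min_donor))

  vals["G1"] <- with_descriptor("G1", bite_angle(
    complex_structure, metal, donors$min_donor, donors$max_donor))
  vals["G2"] <- with_descriptor("G2", exact_cone_angle(
    complex_structure, metal, lig)$angle)
  mids <- with_descriptor("G3", olefin_midpoints(complex_structure, part,
                                                 graph))
  vals["G3"] <- with_descriptor("G3", dihedral_points(
    xyz[donors$min_donor, ], xyz[metal, ], mids$mid1, mids$mid2))
  vals["G4"] <- with_descriptor("G4", atom_distance(
    complex_structure, metal, donors$min_donor))
  vals["G5"] <- with_descriptor("G5", atom_distance(
    complex_structure, metal, donors$max_donor))
  vals["G6"] <- with_descriptor("G6", atom_distance(
    complex_structure, donors$min_donor, donors$max_donor))
  vals["G7"] <- with_descriptor("G7",
                                sqrt(sum((mids$mid1 - xyz[metal, ])^2)))
  vals["G8"] <- with_descriptor("G8",
                                sqrt(sum((mids$mid2 - xyz[metal, ])^2)))

  scx <- sidecar_complex
  scf <- sidecar_free_ligand
  fmin <- to_free(donors$min_donor)
  fmax <- to_free(donors$max_donor)
  vals["E1"] <- scx$homo_lumo_gap
  vals["E2"] <- sidecar_value(scx, "nbo_charge", donors$min_donor, "E2")
  vals["E3"] <- sidecar_value(scx, "nbo_charge", donors$max_donor, "E3")
  vals["E4"] <- sidecar_value(scx, "lone_pair_occupancy", donors$min_donor,
                              "E4")
  vals["E5"] <- sidecar_value(scx, "nbo_charge", metal, "E5")
  vals["E6"] <- sidecar_value(scx, "lone_pair_occupancy", donors$max_donor,
                              "E6")
  vals["E7"] <- sidecar_value(scf, "lone_pair_occupancy", fmin, "E7")
  vals["E8"] <- sidecar_value(scf, "lone_pair_occupancy", fmax, "E8")
  vals["E9"] <- sidecar_value(scf, "nbo_charge", fmin, "E9")
  vals["E10"] <- sidecar_value(scf, "nbo_charge", fmax, "E10")
  vals["E11"] <- scf$homo_lumo_gap

  schema <- catalyst_schema()
  stopifnot(identical(sort(names(vals)), sort(schema$name)))
  out <- tibble::as_tibble(as.list(vals[schema$name]))
  dplyr::bind_cols(
    tibble::tibble(ligand_id = ligand_id %||% complex_structure$id),
    out
  )
}

#' Featurize a ligand library from a manifest
#'
#' @param manifest A data frame (or path to a YAML file with a `ligands`
#'   list) with columns/fields `ligand_id`, `xyz`, `sidecar_complex`,
#'   `sidecar_free_ligand` giving file paths.
#' @param ... Passed on to [featurize_catalyst()].
#' @return Tibble with one row per successfully featurized ligand, columns
#'   in schema order.  Per-ligand failures do not abort the batch; they are
#'   collected in the `failures` attribute (tibble `ligand_id`, `error`)
#'   and summarised in a message.
#' @export
featurize_library <- function(manifest, ...) {
  if (is.character(manifest) && length(manifest) == 1) {
    raw <- yaml::read_yaml(manifest)
    manifest <- dplyr::bind_rows(lapply(raw$ligands, tibble::as_tibble))
  }
  manifest <- tibble::as_tibble(manifest)
  need <- c("ligand_id", "xyz", "sidecar_complex", "sidecar_free_ligand")
  missing <- setdiff(need, names(manifest))
  if (length(missing)) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- vector("list", nrow(manifest))
  fails <- list()
  for (k in seq_len(nrow(manifest))) {
    m <- manifest[k, ]
    res <- tryCatch({
      st <- read_xyz(m$xyz)
      scx <- read_sidecar(m$sidecar_complex, structure = st)
      scf <- read_sidecar(m$sidecar_free_ligand)
      featurize_catalyst(st, scx, scf, ligand_id = m$ligand_id, ...)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1]] <- tibble::tibble(
        ligand_id = m$ligand_id, error = conditionMessage(res))
    } else {
      rows[[k]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  failures <- dplyr::bind_rows(fails)
  if (nrow(failures)) {
    message(nrow(failures), " ligand(s) failed featurization; see the ",
            "'failures' attribute")
  }
  attr(out, "failures") <- failures
  out
}

#' Write a descriptor table to CSV
#'
#' @param descriptors Tibble from [featurize_library()] or
#'   [generate_descriptor_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(descriptors, path) {
  readr::write_csv(descriptors, path, progress = FALSE)
  invisible(path)
}
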