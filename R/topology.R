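# Bond perception and complex partitioning.
#
# A bonding graph is perceived from geometry with the covalent-radii rule
# (edge iff the interatomic distance is at most `scale` times the radii
# sum).  The graph is then used to split a [Rh(L)(NBD)]+ precatalyst into
# its metal centre, donor-bearing ligand and auxiliary diene, which is the
# basis for ligand-only steric descriptors.

#' Perceive the bonding graph of a structure
#'
#' Edge rule: atoms i and j are bonded iff
#' `dist(i, j) <= scale * (r_cov(i) + r_cov(j))`, with covalent radii taken
#' from the bundled [element_radii()] table.
#'
#' @param structure An [xyz_structure()].
#' @param scale Multiplier on the covalent-radii sum (default 1.20).
#' @return A `molecular_graph`: list with `n_atoms` and an `edges` tibble
#'   (`i`, `j`, `length` in Angstrom, with `i < j`).
#' @export
build_graph <- function(structure, scale = 1.20) {
  stopifnot(scale > 0)
  n <- n_atoms(structure)
  xyz <- coords_matrix(structure)
  rc <- covalent_radius(structure$atoms$element)
  if (n < 2) {
    edges <- tibble::tibble(i = integer(), j = integer(), length = numeric())
  } else {
    d <- as.matrix(stats::dist(xyz))
    cutoff <- outer(rc, rc, `+`) * scale
    hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
    edges <- tibble::tibble(
      i = as.integer(hit[, 1]),
      j = as.integer(hit[, 2]),
      length = d[hit]
    )
  }
  structure(list(n_atoms = n, edges = edges), class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph: %d atoms, %d bonds>\n",
              x$n_atoms, nrow(x$edges)))
  invisible(x)
}

# igraph view of a molecular graph (isolated atoms kept as vertices).
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("i", "j")],
    directed = FALSE,
    vertices = data.frame(name = seq_len(graph$n_atoms))
  )
}

# Integer component membership for every atom.
graph_components <- function(graph) {
  comp <- igraph::components(as_igraph(graph))
  membership <- comp$membership[as.character(seq_len(graph$n_atoms))]
  as.integer(membership)
}

# Neighbours of atom `v` in the bonding graph.
graph_neighbors <- function(graph, v) {
  e <- graph$edges
  sort(c(e$j[e$i == v], e$i[e$j == v]))
}

#' Partition a precatalyst complex into metal, ligand and auxiliary diene
#'
#' Deletes the (single) metal atom from the bonding graph and classifies the
#' remaining connected components: components bonded to the metal that carry
#' at least one P or N donor within `donor_cutoff` of the metal form the
#' ligand; the metal-bonded component whose heavy atoms are all carbon (the
#' norbornadiene-like diene) is the auxiliary.  Any other metal-bonded
#' component is an error rather than a guess.  If the ligand fragments into
#' several donor components (e.g. two monophosphines) they are unioned and a
#' message is emitted.
#'
#' @param structure An [xyz_structure()] of the full complex.
#' @param graph Its [build_graph()] result.
#' @param metal_symbol Element symbol of the metal centre (default "Rh").
#' @param donor_cutoff Maximum metal-donor distance in Angstrom counted as a
#'   coordination bond (default 2.8, generous for Rh-P / Rh-N).
#' @return A `complex_partition`: list with `metal_index`, `donor_indices`
#'   (sorted), `ligand_atoms`, `auxiliary_atoms`.
#' @export
partition_complex <- function(structure, graph, metal_symbol = "Rh",
                              donor_cutoff = 2.8) {
  el <- structure$atoms$element
  metal <- which(el == metal_symbol)
  if (length(metal) != 1) {
    stop(sprintf("expected exactly one %s atom, found %d",
                 metal_symbol, length(metal)), call. = FALSE)
  }
  metal_neighbors <- graph_neighbors(graph, metal)

  pruned <- graph
  pruned$edges <- dplyr::filter(pruned$edges, .data$i != metal,
                                .data$j != metal)
  membership <- graph_components(pruned)
  membership[metal] <- NA_integer_

  xyz <- coords_matrix(structure)
  dist_to_metal <- sqrt(colSums((t(xyz) - xyz[metal, ])^2))

  ligand_atoms <- integer()
  auxiliary_atoms <- integer()
  donor_indices <- integer()
  n_donor_components <- 0L

  for (comp in unique(stats::na.omit(membership))) {
    atoms <- which(membership == comp)
    if (!any(atoms %in% metal_neighbors)) {
      stop("fragment not bonded to the metal: atoms ",
           paste(utils::head(atoms, 5), collapse = ","),
           if (length(atoms) > 5) ",..." else "", call. = FALSE)
    }
    donors <- atoms[el[atoms] %in% c("P", "N") &
                      dist_to_metal[atoms] <= donor_cutoff]
    heavy <- atoms[el[atoms] != "H"]
    if (length(donors)) {
      ligand_atoms <- c(ligand_atoms, atoms)
      donor_indices <- c(donor_indices, donors)
      n_donor_components <- n_donor_components + 1L
    } else if (length(heavy) && all(el[heavy] == "C")) {
      auxiliary_atoms <- c(auxiliary_atoms, atoms)
    } else {
      stop("metal-bonded fragment is neither a P/N donor ligand nor an ",
           "all-carbon auxiliary (atoms ",
           paste(utils::head(atoms, 5), collapse = ","), ")", call. = FALSE)
    }
  }
  if (!length(donor_indices)) {
    stop("no donor ligand found: no P/N component bonded to the metal",
         call. = FALSE)
  }
  if (n_donor_components > 1L) {
    message("ligand is split over ", n_donor_components,
            " components; treating their union as the ligand")
  }
  structure(
    list(
      metal_index = metal,
      donor_indices = sort(unique(donor_indices)),
      ligand_atoms = sort(ligand_atoms),
      auxiliary_atoms = sort(auxiliary_atoms)
    ),
    class = "complex_partition"
  )
}

#' @export
print.complex_partition <- function(x, ...) {
  cat(sprintf(
    "<complex_partition: metal %d, donors [%s], %d ligand / %d auxiliary atoms>\n",
    x$metal_index, paste(x$donor_indices, collapse = ", "),
    length(x$ligand_atoms), length(x$auxiliary_atoms)
  ))
  invisible(x)
}

#' Label the donors of a bidentate ligand by NBO charge
#'
#' The two coordinating atoms are distinguished by their partial charge:
#' `max_donor` is the most positively charged donor, `min_donor` the least.
#' Ties resolve to the smaller atom index for both roles, and a monodentate
#' ligand duplicates its single donor in both roles.
#'
#' @param partition A [partition_complex()] result.
#' @param sidecar_complex The complex-context [electronic_sidecar()]; must
#'   carry an NBO charge for every donor atom.
#' @return List with `min_donor` and `max_donor` atom indices.
#' @export
assign_donor_labels <- function(partition, sidecar_complex) {
  donors <- partition$donor_indices
  ch <- sidecar_complex$nbo_charge[as.character(donors)]
  if (anyNA(ch)) {
    stop("sidecar is missing an NBO charge for donor atom(s) ",
         paste(donors[is.na(ch)], collapse = ", "), call. = FALSE)
  }
  # which.min/which.max take the first hit, so equal charges fall back to
  # the smaller atom index for both roles
  list(min_donor = donors[which.min(ch)], max_donor = donors[which.max(ch)])
}

#' Extract the free ligand from a partitioned complex
#'
#' Returns a new structure containing exactly the ligand atoms with
#' unchanged coordinates, plus the old-to-new index mapping needed to carry
#' donor labels (and sidecar keys) into the free-ligand numbering.
#'
#' @param structure The complex [xyz_structure()].
#' @param partition Its [partition_complex()] result.
#' @return An [xyz_structure()] with attribute `index_map`, a tibble with
#'   columns `old` and `new`.
#' @export
extract_free_ligand <- function(structure, partition) {
  old <- partition$ligand_atoms
  at <- structure$atoms[old, ]
  out <- xyz_structure(
    paste0(structure$id, "_ligand"),
    at$element,
    as.matrix(at[, c("x", "y", "z")]),
    charge = 0L
  )
  attr(out, "index_map") <- tibble::tibble(old = old,
                                           new = seq_along(old))
  out
}
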