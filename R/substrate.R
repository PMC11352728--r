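# Olefin substrate fingerprints: locate the prochiral C=C site, enumerate
# its four substituent anchors, and compute the 18-feature steric
# fingerprint (6 buried volumes + 12 sterimol parameters).

# Run the bundled rdkit helper; request/response travel as JSON temp files.
run_chemtools <- function(command, request) {
  script <- system.file("python", "chemtools.py", package = "chiralcat",
                        mustWork = TRUE)
  req <- tempfile(fileext = ".json")
  resp <- tempfile(fileext = ".json")
  on.exit(unlink(c(req, resp)), add = TRUE)
  jsonlite::write_json(request, req, auto_unbox = TRUE, digits = NA)
  status <- system2("python", c(script, command, req, resp),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(resp)) {
    stop("chemtools helper failed (command '", command, "')", call. = FALSE)
  }
  out <- jsonlite::read_json(resp, simplifyVector = TRUE)
  if (!is.null(out$error)) stop(out$error, call. = FALSE)
  out
}

#' Embed a 3D structure from SMILES
#'
#' Deterministic distance-geometry embedding (ETKDG with a fixed random
#' seed) followed by MMFF relaxation, via the bundled rdkit helper.  The
#' same seed always yields identical coordinates.
#'
#' @param smiles A single SMILES string.
#' @param seed Embedding seed (default 1).
#' @param id Structure id (defaults to the SMILES).
#' @return An [xyz_structure()] with hydrogens added.  Non-aromatic C=C
#'   bonds perceived from the SMILES are stored in the `double_cc_bonds`
#'   attribute (n x 2 matrix of 1-based atom indices), usable as the
#'   [locate_olefin()] hint.
#' @export
embed_from_smiles <- function(smiles, seed = 1, id = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  out <- run_chemtools("embed", list(smiles = smiles, seed = seed))
  co <- out$coords
  if (is.list(co)) co <- do.call(rbind, lapply(co, as.numeric))
  st <- xyz_structure(id %||% smiles, out$elements,
                      matrix(as.numeric(co), ncol = 3),
                      charge = out$charge %||% 0L)
  bonds <- out$double_cc_bonds
  if (length(bonds)) {
    if (is.list(bonds)) bonds <- do.call(rbind, lapply(bonds, as.integer))
    attr(st, "double_cc_bonds") <- matrix(as.integer(bonds), ncol = 2)
  }
  st
}

#' Locate the reactive olefin and enumerate its substituent anchors
#'
#' Finds the C=C site and returns the two olefin carbons C1, C2 plus the
#' four substituent anchors R1-R4 (R1, R2 on C1; R3, R4 on C2) in canonical
#' order: per carbon, substituents sort by descending atomic number, ties
#' by ascending atom index; hydrogens count as substituents.
#'
#' Without a hint, candidate C=C bonds are perceived geometrically: bonded
#' carbon pairs with bond length at most 1.42 Angstrom, at most three
#' neighbours on each carbon, and the bond not part of a ring (which rules
#' out aromatic carbons but also means olefins inside rings need a hint).
#'
#' @param structure An [xyz_structure()] of the substrate.
#' @param graph Its [build_graph()] result (rebuilt if omitted).
#' @param hint Optional length-2 integer vector of the C1/C2 atom indices;
#'   required when perception finds zero or several candidates.
#' @return List with `C1`, `C2` and `R` (integer vector R1-R4).
#' @export
locate_olefin <- function(structure, graph = NULL, hint = NULL) {
  if (is.null(graph)) graph <- build_graph(structure)
  el <- structure$atoms$element
  if (is.null(hint)) hint <- attr(structure, "double_cc_bonds")
  if (!is.null(hint)) {
    hint <- as.integer(hint)
    if (length(hint) != 2) {
      stop("olefin hint must give exactly two atom indices (one C=C)",
           call. = FALSE)
    }
    c1 <- hint[[1]]; c2 <- hint[[2]]
    if (!all(el[c(c1, c2)] == "C")) {
      stop("olefin hint atoms must both be carbon", call. = FALSE)
    }
  } else {
    e <- graph$edges
    cand <- e[el[e$i] == "C" & el[e$j] == "C" & e$length <= 1.42, ,
              drop = FALSE]
    if (nrow(cand)) {
      deg <- tabulate(c(graph$edges$i, graph$edges$j), graph$n_atoms)
      on_ring <- vapply(seq_len(nrow(cand)), function(k) {
        g2 <- graph
        g2$edges <- g2$edges[!(g2$edges$i == cand$i[k] &
                                 g2$edges$j == cand$j[k]), ]
        memb <- graph_components(g2)
        memb[cand$i[k]] == memb[cand$j[k]] # still connected: bond in a ring
      }, logical(1))
      cand <- cand[deg[cand$i] <= 3 & deg[cand$j] <= 3 & !on_ring, ,
                   drop = FALSE]
    }
    if (nrow(cand) == 0) {
      stop("no C=C candidate found; supply a hint", call. = FALSE)
    }
    if (nrow(cand) > 1) {
      stop("ambiguous olefin site; candidates: ",
           paste(sprintf("(%d,%d)", cand$i, cand$j), collapse = " "),
           "; supply a hint", call. = FALSE)
    }
    c1 <- cand$i[[1]]; c2 <- cand$j[[1]]
  }
  anchors <- function(carbon, other) {
    nb <- setdiff(graph_neighbors(graph, carbon), other)
    if (length(nb) != 2) {
      stop(sprintf("olefin carbon %d has %d substituents, expected 2",
                   carbon, length(nb)), call. = FALSE)
    }
    nb[order(-atomic_number(el[nb]), nb)]
  }
  list(C1 = c1, C2 = c2, R = c(anchors(c1, c2), anchors(c2, c1)))
}

# Atoms reachable from `start` without crossing `blocked`.
branch_atoms <- function(graph, start, blocked) {
  seen <- c(blocked)
  frontier <- start
  out <- integer()
  while (length(frontier)) {
    out <- c(out, frontier)
    seen <- c(seen, frontier)
    frontier <- setdiff(
      unique(unlist(lapply(frontier, graph_neighbors, graph = graph))),
      seen
    )
  }
  sort(out)
}

#' The 18-feature olefin steric fingerprint
#'
#' Six percent buried volumes (3.5 Angstrom spheres centred on C1, C2 and
#' R1-R4, with the whole substrate minus the centre atom as occupying set)
#' plus sterimol B1/B5/L for each of the four C-R pairings, where the
#' sterimol subset is the substituent branch reachable from R without
#' crossing its olefin carbon.
#'
#' @param structure An [xyz_structure()] of the substrate.
#' @param site A [locate_olefin()] result.
#' @param graph Its bonding graph (rebuilt if omitted).
#' @param sphere_radius,radii_scale,grid_spacing Steric conventions, as in
#'   [buried_volume()].
#' @return One-row tibble with 18 columns: `vbur_C1`, `vbur_C2`,
#'   `vbur_R1`..`vbur_R4`, then `L`, `B1`, `B5` for `C1R1`, `C1R2`, `C2R3`,
#'   `C2R4`.
#' @export
substrate_fingerprint <- function(structure, site, graph = NULL,
                                  sphere_radius = 3.5, radii_scale = 1.17,
                                  grid_spacing = 0.05) {
  if (is.null(graph)) graph <- build_graph(structure)
  all_atoms <- seq_len(n_atoms(structure))
  centers <- c(C1 = site$C1, C2 = site$C2,
               R1 = site$R[[1]], R2 = site$R[[2]],
               R3 = site$R[[3]], R4 = site$R[[4]])
  vb <- vapply(centers, function(a) {
    buried_volume(structure, all_atoms, a, sphere_radius = sphere_radius,
                  radii_scale = radii_scale, excluded_atoms = a,
                  grid_spacing = grid_spacing)
  }, numeric(1))
  pairings <- list(
    C1R1 = c(site$C1, site$R[[1]]), C1R2 = c(site$C1, site$R[[2]]),
    C2R3 = c(site$C2, site$R[[3]]), C2R4 = c(site$C2, site$R[[4]])
  )
  ster <- lapply(pairings, function(p) {
    subset <- branch_atoms(graph, p[[2]], blocked = p[[1]])
    sterimol(structure, attach = p[[1]], first = p[[2]],
             atom_subset = subset, radii_scale = radii_scale)
  })
  out <- c(
    as.list(stats::setNames(vb, paste0("vbur_", names(centers)))),
    unlist(lapply(names(ster), function(nm) {
      stats::setNames(ster[[nm]][c("L", "B1", "B5")],
                      paste0(c("L_", "B1_", "B5_"), nm))
    }), recursive = FALSE)
  )
  tibble::as_tibble(out)
}

#' Representative model substrates
#'
#' Five synthetic stand-in substrates (SM1-SM5) spanning the
#' dehydroamino-ester / itaconate / cinnamate classes typical of rhodium
#' asymmetric hydrogenation benchmarks, as SMILES.  They stand in for the
#' five proprietary screening substrates and are used by the synthetic
#' data module and the substrate representations.
#'
#' @return Tibble with `substrate_id` and `smiles`.
#' @export
canonical_substrates <- function() {
  tibble::tribble(
    ~substrate_id, ~smiles,
    "SM1", "COC(=O)C(=C)NC(C)=O",
    "SM2", "COC(=O)/C(=C/c1ccccc1)NC(C)=O",
    "SM3", "OC(=O)C(=C)NC(C)=O",
    "SM4", "COC(=O)CC(=C)C(=O)OC",
    "SM5", "OC(=O)/C(C)=C/c1ccccc1"
  )
}
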