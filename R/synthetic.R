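# Synthetic-data generators: toy precatalyst geometries with electronic
# sidecars, a factor-structured catalyst descriptor table, combinatorial
# ligand SMILES, and HTE outcome tables with the screening campaign's
# statistical signature (bimodal conversion skewed high, near-normal ddG
# in the per-substrate ranges, and the printed inter-substrate rank
# correlations).
#
# Chemical realism of the geometries is explicitly not a goal; geometric
# validity for the descriptor code is.

# Mix a user seed with a per-generator tag so different generators called
# with the same seed draw from decorrelated RNG streams (a shared stream
# would leak descriptor factors into "identity-driven" outcomes).
scramble_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

# Rigid norbornadiene-like C7H8 cage (coordinates frozen from a single
# relaxed conformer).  Atoms 1:7 are carbons; the two olefinic pairs are
# (1,2) and (6,7).
nbd_template <- function() {
  el <- c("C", "C", "C", "C", "C", "C", "C",
          "H", "H", "H", "H", "H", "H", "H", "H")
  xyz <- matrix(c(
     0.9136,  1.1630, -0.3495,
     1.5059, -0.0402, -0.2000,
     0.3953, -1.0636, -0.0288,
    -0.6206, -0.4286, -0.9899,
    -0.5869,  0.9313, -0.2768,
    -0.9293,  0.4383,  1.1197,
    -0.3370, -0.7648,  1.2692,
     1.4014,  2.1199, -0.4465,
     2.5643, -0.2421, -0.1529,
     0.6338, -2.1042, -0.2428,
    -0.2757, -0.3883, -2.0323,
    -1.6071, -0.9118, -0.9709,
    -1.2340,  1.6897, -0.7145,
    -1.4933,  0.9817,  1.8612,
    -0.3305, -1.3803,  2.1547
  ), ncol = 3, byrow = TRUE)
  list(elements = el, coords = xyz, olefin_pairs = rbind(c(1, 2), c(6, 7)))
}

rotation_to_x <- function(v) {
  # orthonormal rotation taking unit(v) onto +x
  v <- v / sqrt(sum(v^2))
  seed <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  e2 <- seed - sum(seed * v) * v
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(v[2] * e2[3] - v[3] * e2[2], v[3] * e2[1] - v[1] * e2[3],
          v[1] * e2[2] - v[2] * e2[1])
  rbind(v, e2, e3)
}

# Tetrahedral-ish hydrogen directions perpendicular to a main axis.
append_hydrogens <- function(atoms, center, axis, n_h, bond = 1.09) {
  axis <- axis / sqrt(sum(axis^2))
  seed <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- seed - sum(seed * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  for (k in seq_len(n_h)) {
    ang <- 2 * pi * (k - 1) / max(1, n_h)
    dirn <- 0.45 * axis + cos(ang) * e1 + sin(ang) * e2
    dirn <- dirn / sqrt(sum(dirn^2))
    atoms[[length(atoms) + 1]] <- list(el = "H", xyz = center + bond * dirn)
  }
  atoms
}

#' Generate a toy precatalyst fixture
#'
#' Builds a geometrically valid stand-in for an optimized `[Rh(L)(NBD)]+`
#' complex: Rh at the origin, two donor atoms at ~2.3 Angstrom realizing
#' the requested bite angle, alkyl arms of the requested bulk on each
#' donor, an ethylene backbone bridging the donors (so the ligand is one
#' bidentate component), and a rigid norbornadiene-like C7H8 cage bonded
#' trans to the donors.  Electronic sidecars are drawn from plausible
#' ranges (gaps 2-6 eV, donor charges +0.4..+1.0, occupancies 1.5-2.0).
#'
#' @param arm_bulk Carbons per donor substituent arm (1 = methyl,
#'   2 = ethyl, 3 = propyl).
#' @param bite_angle_target Donor-metal-donor angle in degrees, in
#'   (60, 140).
#' @param seed RNG seed; the same seed reproduces the fixture exactly.
#' @param donor_elements Length-2 donor symbols, e.g. `c("P", "P")` or
#'   `c("P", "N")`.
#' @param id Structure id.
#' @return List with `structure` (the complex), `sidecar_complex`,
#'   `sidecar_free_ligand` (keyed in free-ligand numbering), and
#'   `bookkeeping` (true `metal`, `donors`, `ligand_atoms`,
#'   `auxiliary_atoms` index sets).
#' @export
generate_complex_fixture <- function(arm_bulk = 1, bite_angle_target = 88,
                                     seed = 1,
                                     donor_elements = c("P", "P"),
                                     id = NULL) {
  if (bite_angle_target <= 60 || bite_angle_target >= 140) {
    stop("infeasible bite angle: must lie in (60, 140) degrees",
         call. = FALSE)
  }
  stopifnot(arm_bulk >= 1, length(donor_elements) == 2,
            all(donor_elements %in% c("P", "N")))
  set.seed(scramble_seed(seed, "fixture"))
  half <- bite_angle_target / 2 * pi / 180
  d_md <- 2.30
  atoms <- list(list(el = "Rh", xyz = c(0, 0, 0)))
  p1 <- d_md * c(cos(half), sin(half), 0)
  p2 <- d_md * c(cos(half), -sin(half), 0)
  atoms[[2]] <- list(el = donor_elements[[1]], xyz = p1)
  atoms[[3]] <- list(el = donor_elements[[2]], xyz = p2)
  donor_idx <- c(2L, 3L)

  # ethylene backbone bridging the donors, lifted out of the donor plane;
  # donor-carbon bond lengths are element-appropriate (P-C 1.84, N-C 1.47)
  donor_c_bond <- ifelse(donor_elements == "N", 1.47, 1.84)
  dpp <- sqrt(sum((p1 - p2)^2))
  mid <- (p1 + p2) / 2
  lifts <- sqrt(pmax(0.2, donor_c_bond^2 - (dpp / 2 - 0.77)^2))
  along <- (p1 - p2) / dpp
  c1 <- mid + 0.77 * along + c(0, 0, lifts[[1]])
  c2 <- mid - 0.77 * along + c(0, 0, lifts[[2]])
  atoms[[4]] <- list(el = "C", xyz = c1)
  atoms[[5]] <- list(el = "C", xyz = c2)
  atoms <- append_hydrogens(atoms, c1, c1 - (p1 + c2) / 2, 2)
  atoms <- append_hydrogens(atoms, c2, c2 - (p2 + c1) / 2, 2)

  # alkyl arms: two chains per donor, pointing away from the metal
  for (di in seq_len(2)) {
    dp <- if (di == 1) p1 else p2
    radial <- dp / sqrt(sum(dp^2))
    for (arm in seq_len(2)) {
      updown <- if (arm == 1) c(0, 0, 1) else c(0, 0, -1)
      dirn <- radial + 0.9 * updown +
        0.15 * c(0, if (di == 1) 1 else -1, 0)
      dirn <- dirn / sqrt(sum(dirn^2))
      prev <- dp
      for (k in seq_len(arm_bulk)) {
        bond <- if (k == 1) donor_c_bond[[di]] else 1.53
        pos <- prev + bond * dirn +
          stats::rnorm(3, sd = 0.01) # tiny seeded jitter
        atoms[[length(atoms) + 1]] <- list(el = "C", xyz = pos)
        n_h <- if (k == arm_bulk) 3 else 2
        atoms <- append_hydrogens(atoms, pos,
                                  if (k == arm_bulk) dirn
                                  else pracma_cross_safe(dirn), n_h)
        prev <- pos
        dirn <- rotate_slightly(dirn)
      }
    }
  }
  n_lig_end <- length(atoms)
  ligand_atoms <- 2:n_lig_end

  # norbornadiene-like cage trans to the donors (-x side)
  nbd <- nbd_template()
  mids <- (nbd$coords[nbd$olefin_pairs[, 1], ] +
             nbd$coords[nbd$olefin_pairs[, 2], ]) / 2
  cage_centroid <- colMeans(nbd$coords[1:7, ])
  face <- colMeans(mids) - cage_centroid
  rot <- rotation_to_x(face)
  coords <- nbd$coords %*% t(rot) # face now points along +x
  mm <- colMeans((coords[nbd$olefin_pairs[, 1], ] +
                    coords[nbd$olefin_pairs[, 2], ]) / 2)
  coords <- sweep(coords, 2, mm + c(2.05, 0, 0)) # midpoints centre -> -2.05 x
  aux_start <- length(atoms) + 1L
  for (k in seq_along(nbd$elements)) {
    atoms[[length(atoms) + 1]] <- list(el = nbd$elements[[k]],
                                       xyz = coords[k, ])
  }
  auxiliary_atoms <- aux_start:length(atoms)

  el <- vapply(atoms, function(a) a$el, character(1))
  xyz <- do.call(rbind, lapply(atoms, function(a) a$xyz))
  id <- id %||% sprintf("toy_%s%s_b%d_a%d_s%d", donor_elements[[1]],
                        donor_elements[[2]], round(bite_angle_target),
                        arm_bulk, seed)
  st <- xyz_structure(id, el, xyz, charge = 1L)

  # electronic sidecars in plausible ranges; donor charges kept distinct
  ch <- sort(stats::runif(2, 0.40, 1.00), decreasing = TRUE)
  if (donor_elements[[2]] == "N" && donor_elements[[1]] == "P") {
    ch <- c(max(ch), stats::runif(1, -0.70, -0.30)) # N donor more negative
  }
  occ <- stats::runif(2, 1.5, 2.0)
  sc_complex <- electronic_sidecar(
    structure_id = id, context = "complex",
    homo_lumo_gap = stats::runif(1, 2, 6),
    nbo_charge = stats::setNames(c(stats::runif(1, -0.3, 0.5), ch),
                                 c(1L, donor_idx)),
    lone_pair_occupancy = stats::setNames(occ, donor_idx)
  )
  free_idx <- match(donor_idx, sort(ligand_atoms))
  sc_free <- electronic_sidecar(
    structure_id = paste0(id, "_ligand"), context = "free_ligand",
    homo_lumo_gap = stats::runif(1, 2, 6),
    nbo_charge = stats::setNames(ch + stats::rnorm(2, sd = 0.05), free_idx),
    lone_pair_occupancy = stats::setNames(
      pmin(2, pmax(0, occ + stats::rnorm(2, sd = 0.03))), free_idx)
  )
  list(
    structure = st,
    sidecar_complex = sc_complex,
    sidecar_free_ligand = sc_free,
    bookkeeping = list(metal = 1L, donors = donor_idx,
                       ligand_atoms = ligand_atoms,
                       auxiliary_atoms = auxiliary_atoms)
  )
}

pracma_cross_safe <- function(v) {
  seed <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- seed - sum(seed * v) * v
  0.8 * v + 0.6 * w / sqrt(sum(w^2))
}

rotate_slightly <- function(v) {
  seed <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  w <- seed - sum(seed * v) * v
  out <- 0.92 * v + 0.39 * w / sqrt(sum(w^2))
  out / sqrt(sum(out^2))
}

#' Combinatorial bidentate phosphine SMILES
#'
#' Deterministic enumeration of `R1R2P-bridge-PR3R4` diphosphines over a
#' small alkyl/aryl substituent alphabet; used as parsable stand-ins for a
#' ligand library when circular fingerprints are required.
#'
#' @param n Number of distinct ligands.
#' @return Tibble with `ligand_id` (`L001`...) and `smiles`.
#' @export
generate_ligand_smiles <- function(n = 192) {
  arms <- c("C", "CC", "CCC", "C(C)C", "CC(C)C", "C1CCCCC1", "c1ccccc1",
            "CCCC")
  bridges <- c("CC", "CCC", "CCCC")
  grid <- expand.grid(a1 = arms, a2 = arms, br = bridges,
                      stringsAsFactors = FALSE)
  grid <- grid[order(nchar(grid$a1) + nchar(grid$a2), grid$br, grid$a1,
                     grid$a2), ]
  if (n > nrow(grid)) stop("at most ", nrow(grid), " distinct ligands",
                           call. = FALSE)
  smiles <- sprintf("%sP(%s)%sP(%s)%s", grid$a1, grid$a2, grid$br,
                    grid$a2, grid$a1)[seq_len(n)]
  tibble::tibble(ligand_id = sprintf("L%03d", seq_len(n)), smiles = smiles)
}

#' Generate a factor-structured catalyst descriptor table
#'
#' Emulates a featurized ligand library: each descriptor category (steric,
#' geometric, electronic) is driven by its own latent factor plus
#' independent noise, mirroring the strong within-category correlations of
#' real descriptor sets.  Used as the "DFT descriptor" table in synthetic
#' benchmarking runs and for planted-factor recovery tests of the PCA
#' cross-sections.
#'
#' @param n_ligands Number of ligands (default 192).
#' @param seed RNG seed.
#' @param factor_loading Correlation of each column with its category
#'   factor.  The default 0.70 reproduces the observed global variance
#'   structure of real catalyst descriptor sets, where the first two
#'   principal components explain about 37 percent of the variance.
#' @return Tibble: `ligand_id` plus the 34 schema columns.  The generating
#'   factors are stored in the `factors` attribute.
#' @export
generate_descriptor_table <- function(n_ligands = 192, seed = 1,
                                      factor_loading = 0.70) {
  set.seed(scramble_seed(seed, "descriptors"))
  schema <- catalyst_schema()
  factors <- matrix(stats::rnorm(n_ligands * 3), ncol = 3,
                    dimnames = list(NULL, c("steric", "geometric",
                                            "electronic")))
  noise_sd <- sqrt(1 - factor_loading^2)
  cols <- lapply(seq_len(nrow(schema)), function(k) {
    f <- factors[, schema$category[[k]]]
    sgn <- if (k %% 2 == 0) -1 else 1
    sgn * factor_loading * f + stats::rnorm(n_ligands, sd = noise_sd)
  })
  names(cols) <- schema$name
  out <- dplyr::bind_cols(
    tibble::tibble(ligand_id = sprintf("L%03d", seq_len(n_ligands))),
    tibble::as_tibble(cols)
  )
  attr(out, "factors") <- factors
  out
}

#' Specification of the synthetic outcome model
#'
#' Defaults encode the screening campaign's published statistical
#' signature: 192 ligands by 5 substrates; ddG rank correlations of
#' ~0.8 among SM1-SM3 and ~0 for SM4/SM5 via shared-factor loadings;
#' per-substrate ddG ranges of -15..15 kJ/mol (SM1-SM3) and -5..7 kJ/mol
#' (SM4, SM5); and bimodal conversion skewed towards full conversion.
#'
#' @param n_ligands Number of ligands (default 192).
#' @param ddg_loading,conv_loading Named per-substrate loadings in \[0, 1\]
#'   on the shared selectivity/activity factors.  The defaults solve the
#'   published pairwise rank correlations (ddG: 0.82/0.83/0.80 and
#'   conversion: 0.59/0.77/0.65 for SM1-SM2/SM1-SM3/SM2-SM3).
#' @param ddg_center,ddg_scale,ddg_range Per-substrate location, scale
#'   (kJ/mol) and clipping range of the ddG distribution.
#' @param conv_slope,conv_shift Logistic steepness and offset mapping the
#'   activity latent to conversion (defaults give >55% of wells above 0.8).
#' @param conv_noise_sd,ddg_noise_sd Per-well replicate noise (conversion
#'   units / kJ mol^-1; ddG noise is applied before clipping so the stated
#'   ranges are hard bounds).
#' @param signal_mode `"identity_driven"` (latents are pure ligand-level
#'   random effects) or `"descriptor_driven"` (shared factors are sparse
#'   linear functions of a descriptor table, so descriptors carry real
#'   signal).
#' @param n_signal_descriptors Number of descriptor columns with nonzero
#'   weight in descriptor-driven mode.
#' @param seed RNG seed.
#' @return An `outcome_spec` list.
#' @export
outcome_spec <- function(n_ligands = 192,
                         ddg_loading = c(SM1 = 0.9226, SM2 = 0.8888,
                                         SM3 = 0.8997, SM4 = 0, SM5 = 0),
                         conv_loading = c(SM1 = 0.836, SM2 = 0.706,
                                          SM3 = 0.921, SM4 = 0, SM5 = 0),
                         ddg_center = c(SM1 = 0, SM2 = 0, SM3 = 0,
                                        SM4 = 1, SM5 = 1),
                         ddg_scale = c(SM1 = 5, SM2 = 5, SM3 = 5,
                                       SM4 = 2, SM5 = 2),
                         ddg_range = list(SM1 = c(-15, 15),
                                          SM2 = c(-15, 15),
                                          SM3 = c(-15, 15),
                                          SM4 = c(-5, 7), SM5 = c(-5, 7)),
                         conv_slope = 4, conv_shift = 0.7,
                         conv_noise_sd = 0.03, ddg_noise_sd = 0.1,
                         signal_mode = c("identity_driven",
                                         "descriptor_driven"),
                         n_signal_descriptors = 5,
                         seed = 1) {
  signal_mode <- match.arg(signal_mode)
  stopifnot(all(ddg_loading >= 0 & ddg_loading <= 1),
            all(conv_loading >= 0 & conv_loading <= 1),
            all(ddg_scale > 0))
  structure(
    list(n_ligands = n_ligands, substrates = names(ddg_loading),
         ddg_loading = ddg_loading, conv_loading = conv_loading,
         ddg_center = ddg_center, ddg_scale = ddg_scale,
         ddg_range = ddg_range, conv_slope = conv_slope,
         conv_shift = conv_shift, conv_noise_sd = conv_noise_sd,
         ddg_noise_sd = ddg_noise_sd, signal_mode = signal_mode,
         n_signal_descriptors = n_signal_descriptors, seed = seed),
    class = "outcome_spec"
  )
}

# Sparse standardized linear combination of descriptor columns.
descriptor_latent <- function(descriptors, n_signal) {
  X <- scale(as.matrix(descriptors[, catalyst_schema()$name]))
  pick <- sample(ncol(X), n_signal)
  w <- sample(c(-1, 1), n_signal, replace = TRUE)
  z <- as.numeric(X[, pick, drop = FALSE] %*% w)
  list(z = as.numeric(scale(z)), columns = colnames(X)[pick], weights = w)
}

#' Generate a full synthetic HTE outcome table
#'
#' Draws the complete screening design of [canonical_design()] (3552
#' wells) under a latent-factor outcome model: each ligand has a shared
#' selectivity skill and activity level; each substrate mixes the shared
#' factor with an idiosyncratic one according to its loading, which
#' reproduces the published inter-substrate rank-correlation structure.
#' ddG values are scaled and clipped to the per-substrate ranges and
#' mapped to ee at the well temperature; conversion is a steep logistic of
#' the activity latent plus noise, yielding the bimodal, high-skewed
#' distribution.  In descriptor-driven mode the shared factors are sparse
#' linear functions of a supplied descriptor table.
#'
#' @param spec An [outcome_spec()].
#' @param descriptors Descriptor table (required in descriptor-driven
#'   mode), e.g. from [generate_descriptor_table()].
#' @param design Design table; defaults to [canonical_design()].
#' @return A validated HTE tibble of `sum(design$n_points)` records.  The
#'   per-ligand/substrate latents and any descriptor weights are stored in
#'   the `model` attribute.
#' @export
generate_outcomes <- function(spec = outcome_spec(), descriptors = NULL,
                              design = canonical_design()) {
  set.seed(scramble_seed(spec$seed, "outcomes"))
  n <- spec$n_ligands
  subs <- spec$substrates
  ligand_ids <- sprintf("L%03d", seq_len(n))

  if (spec$signal_mode == "descriptor_driven") {
    if (is.null(descriptors)) {
      stop("descriptor-driven mode needs a descriptor table", call. = FALSE)
    }
    stopifnot(nrow(descriptors) == n)
    sel <- descriptor_latent(descriptors, spec$n_signal_descriptors)
    act <- descriptor_latent(descriptors, spec$n_signal_descriptors)
    z_sel <- sel$z
    z_act <- act$z
    weights <- list(selectivity = sel[c("columns", "weights")],
                    activity = act[c("columns", "weights")])
  } else {
    z_sel <- stats::rnorm(n)
    z_act <- stats::rnorm(n)
    weights <- NULL
  }

  per_substrate <- function(shared, loading) {
    eps <- stats::rnorm(n)
    loading * shared + sqrt(1 - loading^2) * eps
  }
  u_sel <- vapply(subs, function(s) per_substrate(z_sel,
                                                  spec$ddg_loading[[s]]),
                  numeric(n))
  u_act <- vapply(subs, function(s) per_substrate(z_act,
                                                  spec$conv_loading[[s]]),
                  numeric(n))
  ddg <- vapply(subs, function(s) {
    rng <- spec$ddg_range[[s]]
    pmin(rng[[2]], pmax(rng[[1]],
                        spec$ddg_center[[s]] +
                          spec$ddg_scale[[s]] * u_sel[, s]))
  }, numeric(n))

  rows <- vector("list", nrow(design))
  for (k in seq_len(nrow(design))) {
    d <- design[k, ]
    reps <- max(1L, d$n_points %/% n)
    lig <- rep(seq_len(min(n, d$n_points)), reps)
    temp_k <- d$temperature_c + 273.15
    s <- d$substrate_id
    conv <- stats::plogis(spec$conv_slope *
                            (u_act[lig, s] + spec$conv_shift)) +
      stats::rnorm(length(lig), sd = spec$conv_noise_sd)
    rng <- spec$ddg_range[[s]]
    ddg_rec <- pmin(rng[[2]], pmax(rng[[1]], ddg[lig, s] +
      stats::rnorm(length(lig), sd = spec$ddg_noise_sd)))
    ee <- ddg_to_ee(ddg_rec, temp_k)
    rows[[k]] <- tibble::tibble(
      ligand_id = ligand_ids[lig],
      substrate_id = s,
      solvent = d$solvent,
      temperature = temp_k,
      pressure = d$pressure_bar,
      time = d$time_h,
      conversion = pmin(1, pmax(0, conv)),
      ee = ee
    )
  }
  out <- validate_hte(dplyr::bind_rows(rows))
  attr(out, "model") <- list(z_sel = z_sel, z_act = z_act, ddg = ddg,
                             weights = weights, spec = spec)
  out
}
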