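# Steric and geometric descriptors: percent buried volume (total and per
# quadrant), the exact cone angle, sterimol B1/B5/L, bite angle, the diene
# dihedral, distances and centroids.
#
# One radii convention is used throughout the steric code: van der Waals
# radii from element_radii() scaled by `radii_scale` (default 1.17), the
# dominant community convention for percent buried volume.

#' Default steric conventions
#'
#' @return Named list of the package-wide steric constants: `radii_scale`
#'   (van der Waals scaling, 1.17), `sphere_radius` (probe sphere, 3.5
#'   Angstrom), `grid_spacing` (0.05 Angstrom) and `graph_scale`
#'   (covalent-radii bond-perception multiplier, 1.20).
#' @export
steric_defaults <- function() {
  list(radii_scale = 1.17, sphere_radius = 3.5, grid_spacing = 0.05,
       graph_scale = 1.20)
}

resolve_center <- function(structure, center) {
  if (length(center) == 1 && is.numeric(center) && center == round(center)) {
    xyz <- coords_matrix(structure)
    return(xyz[as.integer(center), ])
  }
  if (length(center) == 3) return(as.numeric(center))
  stop("`center` must be an atom index or a 3-vector", call. = FALSE)
}

# Shared grid accumulation for total and quadrant buried volumes.  The probe
# sphere is voxelised slice-by-slice on a half-offset cubic grid (no grid
# point sits exactly on a frame plane), and voxels covered by any scaled
# vdW sphere of the subset are counted.  `axes`, when given, is a 3x3
# orthonormal matrix whose rows define the quadrant frame.
vbur_grid_count <- function(rel_coords, radii, sphere_radius, grid_spacing,
                            axes = NULL) {
  if (!is.null(axes)) rel_coords <- rel_coords %*% t(axes)
  h <- grid_spacing
  m <- 2L * as.integer(ceiling(sphere_radius / h))
  ax <- (seq_len(m) - (m + 1) / 2) * h
  gx <- rep(ax, times = m)
  gy <- rep(ax, each = m)
  gxy2 <- gx^2 + gy^2
  quadrant_of <- 1L + (gx < 0) + 2L * (gy < 0) # ++, -+, --, +- -> 1,2,3,4
  r2 <- sphere_radius^2

  n_in <- numeric(4)
  n_cov <- numeric(4)
  keep <- logical(length(gx))
  for (z in ax) {
    rz2 <- r2 - z^2
    if (rz2 <= 0) next
    in_sphere <- gxy2 <= rz2
    covered <- keep & FALSE
    if (nrow(rel_coords)) {
      dz <- z - rel_coords[, 3]
      active <- which(abs(dz) < radii)
      for (a in active) {
        ra2 <- radii[a]^2 - dz[a]^2
        covered <- covered |
          ((gx - rel_coords[a, 1])^2 + (gy - rel_coords[a, 2])^2 <= ra2)
      }
    }
    qi <- quadrant_of[in_sphere]
    n_in <- n_in + tabulate(qi, 4)
    qc <- quadrant_of[in_sphere & covered]
    n_cov <- n_cov + tabulate(qc, 4)
  }
  list(n_in = n_in, n_covered = n_cov)
}

prepare_vbur_atoms <- function(structure, atom_subset, center_xyz,
                               radii_scale, include_hydrogens,
                               excluded_atoms) {
  atom_subset <- setdiff(as.integer(atom_subset), as.integer(excluded_atoms))
  el <- structure$atoms$element[atom_subset]
  if (!include_hydrogens) {
    atom_subset <- atom_subset[el != "H"]
    el <- el[el != "H"]
  }
  if (!length(atom_subset)) {
    return(list(rel = matrix(numeric(), 0, 3), radii = numeric()))
  }
  xyz <- coords_matrix(structure)[atom_subset, , drop = FALSE]
  list(rel = sweep(xyz, 2, center_xyz), radii = radii_scale * vdw_radius(el))
}

#' Percent buried volume
#'
#' Fraction (in percent) of a probe sphere occupied by the scaled van der
#' Waals spheres of a chosen atom set, computed on a cubic voxel grid.  For
#' ligand sterics the subset is the ligand atoms only, with the metal or a
#' donor atom as sphere centre.
#'
#' @param structure An [xyz_structure()].
#' @param atom_subset Atom indices whose spheres count as occupied.
#' @param center Sphere centre: an atom index or a 3-vector (Angstrom).
#' @param sphere_radius Probe sphere radius in Angstrom (default 3.5).
#' @param radii_scale van der Waals scaling factor (default 1.17).
#' @param include_hydrogens Count hydrogen spheres (default TRUE).
#' @param excluded_atoms Indices removed from the subset before computing
#'   (e.g. the centre atom itself).
#' @param grid_spacing Voxel edge in Angstrom (default 0.05).
#' @return Percent buried volume in \[0, 100\].
#' @export
#' @examples
#' s <- xyz_structure("probe", "C", matrix(c(0, 0, 0), 1))
#' buried_volume(s, 1, center = c(0, 0, 0)) # single sphere at the centre
buried_volume <- function(structure, atom_subset, center,
                          sphere_radius = 3.5, radii_scale = 1.17,
                          include_hydrogens = TRUE,
                          excluded_atoms = integer(),
                          grid_spacing = 0.05) {
  stopifnot(sphere_radius > 0, radii_scale > 0, grid_spacing > 0)
  center_xyz <- resolve_center(structure, center)
  prep <- prepare_vbur_atoms(structure, atom_subset, center_xyz,
                             radii_scale, include_hydrogens, excluded_atoms)
  counts <- vbur_grid_count(prep$rel, prep$radii, sphere_radius, grid_spacing)
  100 * sum(counts$n_covered) / sum(counts$n_in)
}

#' Quadrant-resolved percent buried volume
#'
#' Splits the probe sphere into four quadrants in a frame anchored on the
#' complex: z runs from the centre (the metal) toward the donor midpoint and
#' the xz-plane contains `xz_atom` (conventionally the max donor).  The mean
#' of the four quadrant percentages equals the total buried volume up to
#' grid resolution.
#'
#' @inheritParams buried_volume
#' @param z_target 3-vector or atom index the +z axis points at.
#' @param xz_atom Atom index pinned into the xz half-plane (x > 0).
#' @return Tibble with columns `quadrant` (`"x+y+"`, `"x-y+"`, `"x-y-"`,
#'   `"x+y-"`) and `vbur`.
#' @export
quadrant_buried_volume <- function(structure, atom_subset, center, z_target,
                                   xz_atom, sphere_radius = 3.5,
                                   radii_scale = 1.17,
                                   include_hydrogens = TRUE,
                                   excluded_atoms = integer(),
                                   grid_spacing = 0.05) {
  center_xyz <- resolve_center(structure, center)
  z_xyz <- resolve_center(structure, z_target)
  x_xyz <- resolve_center(structure, xz_atom)
  ez <- z_xyz - center_xyz
  if (sqrt(sum(ez^2)) < 1e-8) {
    stop("degenerate frame: z target coincides with the centre",
         call. = FALSE)
  }
  ez <- ez / sqrt(sum(ez^2))
  vx <- (x_xyz - center_xyz)
  vx <- vx - sum(vx * ez) * ez
  if (sqrt(sum(vx^2)) < 1e-8) {
    stop("degenerate frame: xz atom is collinear with the z axis",
         call. = FALSE)
  }
  ex <- vx / sqrt(sum(vx^2))
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  axes <- rbind(ex, ey, ez)

  prep <- prepare_vbur_atoms(structure, atom_subset, center_xyz,
                             radii_scale, include_hydrogens, excluded_atoms)
  counts <- vbur_grid_count(prep$rel, prep$radii, sphere_radius,
                            grid_spacing, axes = axes)
  tibble::tibble(
    quadrant = c("x+y+", "x-y+", "x+y-", "x-y-"),
    vbur = 100 * counts$n_covered / counts$n_in
  )
}

#' Exact cone angle
#'
#' Minimal apex angle of a cone with apex at `apex` (the metal) containing
#' every scaled van der Waals sphere of the subset.  For an axis direction
#' u the required full angle is `2 * max_i (angle(u, v_i) + asin(r_i/d_i))`;
#' the axis is found by a Fibonacci-sphere scan followed by Nelder-Mead
#' refinement, which reproduces the one- and two-atom closed forms.
#'
#' @param structure An [xyz_structure()].
#' @param apex Apex atom index.
#' @param atom_subset Atom indices to enclose (e.g. the ligand atoms).
#' @param radii_scale van der Waals scaling factor (default 1.17).
#' @param n_coarse Number of coarse-scan axis directions (default 4096).
#' @return List with `angle` (degrees) and `axis` (unit 3-vector).
#' @export
exact_cone_angle <- function(structure, apex, atom_subset,
                             radii_scale = 1.17, n_coarse = 4096) {
  atom_subset <- setdiff(as.integer(atom_subset), as.integer(apex))
  if (!length(atom_subset)) stop("empty atom subset", call. = FALSE)
  xyz <- coords_matrix(structure)
  v <- sweep(xyz[atom_subset, , drop = FALSE], 2, xyz[as.integer(apex), ])
  d <- sqrt(rowSums(v^2))
  r <- radii_scale * vdw_radius(structure$atoms$element[atom_subset])
  if (any(d <= r)) {
    stop("cone undefined: an atom's van der Waals sphere engulfs the apex",
         call. = FALSE)
  }
  vhat <- v / d
  beta <- asin(r / d)

  half_angle <- function(u) {
    cosang <- pmin(1, pmax(-1, vhat %*% u))
    max(acos(cosang) + beta)
  }

  # coarse scan: Fibonacci sphere plus the atom directions themselves
  k <- seq_len(n_coarse)
  phi <- (1 + sqrt(5)) / 2
  zc <- 1 - (2 * k - 1) / n_coarse
  rho <- sqrt(pmax(0, 1 - zc^2))
  th <- 2 * pi * k / phi
  dirs <- rbind(cbind(rho * cos(th), rho * sin(th), zc), vhat,
                colSums(vhat) / max(1e-12, sqrt(sum(colSums(vhat)^2))))
  vals <- apply(dirs, 1, half_angle)

  to_sph <- function(u) c(acos(pmin(1, pmax(-1, u[3]))), atan2(u[2], u[1]))
  from_sph <- function(p) c(sin(p[1]) * cos(p[2]), sin(p[1]) * sin(p[2]),
                            cos(p[1]))
  best <- list(value = Inf, par = NULL)
  for (i in order(vals)[seq_len(5)]) {
    fit <- stats::optim(to_sph(dirs[i, ]),
                        function(p) half_angle(from_sph(p)),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-13, maxit = 2000))
    if (fit$value < best$value) best <- fit
  }
  axis <- from_sph(best$par)
  list(angle = 2 * best$value * 180 / pi, axis = axis)
}

#' Sterimol parameters B1, B5 and L
#'
#' Substituent shape relative to the attachment axis (the unit vector from
#' `attach` to `first`).  All lengths are measured from the attachment atom
#' with the same scaled van der Waals radii as the buried-volume code:
#' L is the maximal axial extent (projection + radius), B5 the maximal
#' perpendicular extent, and B1 the minimal width of the projected shadow
#' over a 0.1-degree rotational scan of supporting half-planes.
#'
#' @param structure An [xyz_structure()].
#' @param attach Attachment-point atom index (excluded from the subset).
#' @param first First atom of the substituent, defining the axis.
#' @param atom_subset Substituent atom indices (should include `first`).
#' @param radii_scale van der Waals scaling factor (default 1.17).
#' @param n_scan Number of rotational scan directions (default 3600).
#' @return List with `L`, `B1`, `B5` in Angstrom.
#' @export
sterimol <- function(structure, attach, first, atom_subset,
                     radii_scale = 1.17, n_scan = 3600) {
  attach <- as.integer(attach); first <- as.integer(first)
  if (attach == first) stop("`attach` and `first` must differ", call. = FALSE)
  atom_subset <- setdiff(as.integer(atom_subset), attach)
  if (!length(atom_subset)) stop("empty atom subset", call. = FALSE)
  xyz <- coords_matrix(structure)
  a <- xyz[first, ] - xyz[attach, ]
  na <- sqrt(sum(a^2))
  if (na < 1e-8) stop("zero-length sterimol axis", call. = FALSE)
  a <- a / na

  rel <- sweep(xyz[atom_subset, , drop = FALSE], 2, xyz[attach, ])
  r <- radii_scale * vdw_radius(structure$atoms$element[atom_subset])
  proj <- as.numeric(rel %*% a)
  perp <- rel - outer(proj, a)
  pn <- sqrt(rowSums(perp^2))

  L <- max(proj + r)
  B5 <- max(pn + r)

  # orthonormal basis of the plane perpendicular to the axis
  seed <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- seed - sum(seed * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2], a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  u <- as.numeric(perp %*% e1)
  w <- as.numeric(perp %*% e2)
  ang <- 2 * pi * seq_len(n_scan) / n_scan
  # width of the supporting half-plane in each scan direction
  widths <- vapply(ang, function(t) {
    max(u * cos(t) + w * sin(t) + r)
  }, numeric(1))
  list(L = L, B1 = min(widths), B5 = B5)
}

#' Bite angle
#'
#' Donor-metal-donor angle in degrees.
#'
#' @param structure An [xyz_structure()].
#' @param metal,donor_a,donor_b Atom indices of the three distinct atoms.
#' @return Angle at the metal in degrees, in (0, 180\].
#' @export
bite_angle <- function(structure, metal, donor_a, donor_b) {
  xyz <- coords_matrix(structure)
  v1 <- xyz[donor_a, ] - xyz[metal, ]
  v2 <- xyz[donor_b, ] - xyz[metal, ]
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-8 || n2 < 1e-8) {
    stop("coincident atoms: bite angle undefined", call. = FALSE)
  }
  acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

# Signed dihedral of four points, in (-180, 180].
dihedral_points <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Locate the two metal-facing olefinic C-C bonds of the auxiliary diene and
# return their midpoints, nearest first.
olefin_midpoints <- function(structure, partition, graph) {
  aux <- partition$auxiliary_atoms
  e <- graph$edges
  keep <- e$i %in% aux & e$j %in% aux &
    structure$atoms$element[e$i] == "C" & structure$atoms$element[e$j] == "C"
  e <- e[keep, , drop = FALSE]
  if (nrow(e) < 2) stop("diene midpoints not identifiable", call. = FALSE)
  xyz <- coords_matrix(structure)
  mids <- (xyz[e$i, , drop = FALSE] + xyz[e$j, , drop = FALSE]) / 2
  dm <- sqrt(colSums((t(mids) - xyz[partition$metal_index, ])^2))
  ord <- order(dm)
  pick <- ord[[1]]
  # second-nearest bond sharing no atom with the first
  second <- NA_integer_
  for (k in ord[-1]) {
    if (length(intersect(c(e$i[pick], e$j[pick]), c(e$i[k], e$j[k]))) == 0) {
      second <- k
      break
    }
  }
  if (is.na(second)) stop("diene midpoints not identifiable", call. = FALSE)
  list(mid1 = mids[pick, ], mid2 = mids[second, ],
       bonds = e[c(pick, second), c("i", "j")])
}

#' Dihedral of the auxiliary diene relative to the donor atoms
#'
#' Signed four-point dihedral min_donor - metal - olefin-midpoint-1 -
#' olefin-midpoint-2, where the midpoints are those of the two metal-facing
#' C=C bonds of the auxiliary diene (the two auxiliary C-C bonded pairs
#' nearest the metal).  The sign flips for the mirror-image complex, making
#' this the only chirality-sensitive catalyst descriptor.
#'
#' @param structure An [xyz_structure()] of the complex.
#' @param partition Its [partition_complex()] result.
#' @param donors An [assign_donor_labels()] result.
#' @param graph Optional pre-built bonding graph (rebuilt if omitted).
#' @return Signed dihedral in degrees, in (-180, 180\].
#' @export
nbd_dihedral <- function(structure, partition, donors, graph = NULL) {
  if (is.null(graph)) graph <- build_graph(structure)
  mids <- olefin_midpoints(structure, partition, graph)
  xyz <- coords_matrix(structure)
  dihedral_points(xyz[donors$min_donor, ], xyz[partition$metal_index, ],
                  mids$mid1, mids$mid2)
}

#' Interatomic distance
#' @param structure An [xyz_structure()].
#' @param i,j Atom indices.
#' @return Euclidean distance in Angstrom.
#' @export
atom_distance <- function(structure, i, j) {
  xyz <- coords_matrix(structure)
  sqrt(sum((xyz[i, ] - xyz[j, ])^2))
}

#' Centroid of an atom set
#' @param structure An [xyz_structure()].
#' @param atom_subset Atom indices.
#' @return 3-vector centroid (Angstrom).
#' @export
centroid <- function(structure, atom_subset) {
  colMeans(coords_matrix(structure)[as.integer(atom_subset), , drop = FALSE])
}
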