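# Shared fixture builders and independent oracles.  Everything is built in
# code at test time; no binary fixtures.

mk <- function(elements, coords, id = "fix", charge = 0L) {
  xyz_structure(id, elements, matrix(coords, ncol = 3, byrow = TRUE),
                charge = charge)
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_q) < 0) qr_q[, 1] <- -qr_q[, 1]
  qr_q
}

# Monte-Carlo rejection-sampling oracle for percent buried volume.
mc_buried_volume <- function(structure, atom_subset, center, sphere_radius,
                             radii_scale = 1.17, n_points = 1e6,
                             seed = 42) {
  set.seed(seed)
  xyz <- coords_matrix(structure)[atom_subset, , drop = FALSE]
  r <- radii_scale * vdw_radius(structure$atoms$element[atom_subset])
  # uniform points in the sphere via radius inversion
  u <- matrix(rnorm(3 * n_points), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- u * (sphere_radius * runif(n_points)^(1 / 3))
  pts <- sweep(pts, 2, center, `+`)
  covered <- rep(FALSE, n_points)
  for (a in seq_len(nrow(xyz))) {
    covered <- covered |
      (rowSums(sweep(pts, 2, xyz[a, ])^2) <= r[[a]]^2)
  }
  100 * mean(covered)
}

# Brute-force axis-scan oracle for the exact cone angle.
bf_cone_angle <- function(structure, apex, atom_subset, radii_scale = 1.17,
                          n_dirs = 1e6) {
  xyz <- coords_matrix(structure)
  v <- sweep(xyz[atom_subset, , drop = FALSE], 2, xyz[apex, ])
  d <- sqrt(rowSums(v^2))
  r <- radii_scale * vdw_radius(structure$atoms$element[atom_subset])
  vhat <- v / d
  beta <- asin(r / d)
  k <- seq_len(n_dirs)
  phi <- (1 + sqrt(5)) / 2
  z <- 1 - (2 * k - 1) / n_dirs
  rho <- sqrt(pmax(0, 1 - z^2))
  th <- 2 * pi * k / phi
  dirs <- cbind(rho * cos(th), rho * sin(th), z)
  ang <- acos(pmin(pmax(dirs %*% t(vhat), -1), 1))
  per_dir <- do.call(pmax, lapply(seq_along(beta),
                                  function(j) ang[, j] + beta[[j]]))
  2 * min(per_dir) * 180 / pi
}

# Brute-force projection-scan oracle for sterimol.
bf_sterimol <- function(structure, attach, first, atom_subset,
                        radii_scale = 1.17, n_dirs = 36000) {
  xyz <- coords_matrix(structure)
  a <- xyz[first, ] - xyz[attach, ]
  a <- a / sqrt(sum(a^2))
  rel <- sweep(xyz[atom_subset, , drop = FALSE], 2, xyz[attach, ])
  r <- radii_scale * vdw_radius(structure$atoms$element[atom_subset])
  proj <- as.numeric(rel %*% a)
  perp <- rel - outer(proj, a)
  seed <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- seed - sum(seed * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2], a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  u <- as.numeric(perp %*% e1)
  w <- as.numeric(perp %*% e2)
  tt <- 2 * pi * seq_len(n_dirs) / n_dirs
  widths <- vapply(tt, function(t) max(u * cos(t) + w * sin(t) + r),
                   numeric(1))
  list(L = max(proj + r), B1 = min(widths),
       B5 = max(sqrt(rowSums(perp^2)) + r))
}

# Hand-built planar ethylene (C=C 1.33, C-H 1.09, 120-degree angles).
make_ethylene <- function() {
  h <- 1.09
  mk(c("C", "C", "H", "H", "H", "H"), c(
    0, 0, 0,
    1.33, 0, 0,
    -h * cos(pi / 3), h * sin(pi / 3), 0,
    -h * cos(pi / 3), -h * sin(pi / 3), 0,
    1.33 + h * cos(pi / 3), h * sin(pi / 3), 0,
    1.33 + h * cos(pi / 3), -h * sin(pi / 3), 0
  ), id = "ethylene")
}

# Propene: ethylene with one hydrogen replaced by a methyl carbon + 3 H.
make_propene <- function() {
  eth <- make_ethylene()
  at <- eth$atoms
  cm <- c(-1.50 * cos(pi / 3), 1.50 * sin(pi / 3), 0)
  at <- at[-3, ] # drop the H that the methyl replaces
  at <- rbind(at, data.frame(element = "C", x = cm[1], y = cm[2], z = cm[3]))
  hdir <- rbind(c(-1, 0.4, 0), c(-0.2, 1, 0.8), c(-0.2, 1, -0.8))
  for (k in 1:3) {
    d <- hdir[k, ] / sqrt(sum(hdir[k, ]^2))
    at <- rbind(at, data.frame(element = "H", x = cm[1] + 1.09 * d[1],
                               y = cm[2] + 1.09 * d[2],
                               z = cm[3] + 1.09 * d[3]))
  }
  xyz_structure("propene", at$element, as.matrix(at[, c("x", "y", "z")]))
}

# Small valid HTE tibble.
make_hte_records <- function(n = 4) {
  tibble::tibble(
    ligand_id = sprintf("L%03d", seq_len(n)),
    substrate_id = "SM1", solvent = "MeOH",
    temperature = 298.15, pressure = 5, time = 1,
    conversion = seq(0.1, 0.9, length.out = n),
    ee = seq(-0.5, 0.5, length.out = n)
  )
}
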