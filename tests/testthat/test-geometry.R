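# Steric and geometric descriptor oracles.

test_that("buried volume matches the closed-form single-sphere ratio", {
  s <- mk("C", c(0, 0, 0))
  r <- 1.17 * 1.70
  expect_equal(buried_volume(s, 1, center = c(0, 0, 0), sphere_radius = 3.5),
               100 * (r / 3.5)^3, tolerance = 0.5 / 100 * (r / 3.5)^3 + 0.5)
  expect_equal(buried_volume(s, integer(), center = c(0, 0, 0)), 0)
})

test_that("buried volume agrees with a Monte-Carlo rejection oracle", {
  s <- mk(c("P", "C"), c(0.8, 0.3, 0.2, 2.1, -0.4, 0.9))
  got <- buried_volume(s, 1:2, center = c(0, 0, 0), sphere_radius = 3.5)
  oracle <- mc_buried_volume(s, 1:2, c(0, 0, 0), 3.5, n_points = 1e6)
  expect_equal(got, oracle, tolerance = 0.5 / got)
})

test_that("buried volume is monotone in the subset and rotation-invariant", {
  set.seed(3)
  s <- xyz_structure("cloud", rep(c("C", "H"), 5),
                     matrix(rnorm(30, sd = 1.5), ncol = 3))
  v_part <- buried_volume(s, 1:4, center = c(0, 0, 0))
  v_full <- buried_volume(s, 1:10, center = c(0, 0, 0))
  expect_gte(v_full, v_part)
  expect_gte(v_part, 0)
  expect_lte(v_full, 100)
  rot <- random_rotation(5)
  s_rot <- chiralcat:::rotate_structure(s, rot)
  v_rot <- buried_volume(s_rot, 1:10, center = c(0, 0, 0))
  expect_equal(v_rot, v_full, tolerance = 0.3 / v_full)
})

test_that("quadrant buried volumes respect symmetry and conservation", {
  # single atom on the +x axis of the frame: only x>0 quadrants occupied
  s <- mk(c("Rh", "P", "C"), c(0, 0, 0, 0, 0, 2.3, 2.0, 0, 0))
  q <- quadrant_buried_volume(s, 3, center = 1, z_target = 2, xz_atom = 3)
  expect_gt(q$vbur[q$quadrant == "x+y+"], 0)
  expect_gt(q$vbur[q$quadrant == "x+y-"], 0)
  expect_equal(q$vbur[q$quadrant == "x+y+"], q$vbur[q$quadrant == "x+y-"],
               tolerance = 0.05)
  expect_equal(sum(q$vbur[startsWith(q$quadrant, "x-")]), 0)

  # mean of the quadrants equals the total
  fx <- generate_complex_fixture(arm_bulk = 2, seed = 12)
  p <- partition_complex(fx$structure, build_graph(fx$structure))
  da <- assign_donor_labels(p, fx$sidecar_complex)
  xyz <- coords_matrix(fx$structure)
  mid <- (xyz[da$min_donor, ] + xyz[da$max_donor, ]) / 2
  q2 <- quadrant_buried_volume(fx$structure, p$ligand_atoms,
                               center = p$metal_index, z_target = mid,
                               xz_atom = da$max_donor)
  tot <- buried_volume(fx$structure, p$ligand_atoms,
                       center = p$metal_index)
  expect_equal(mean(q2$vbur), tot, tolerance = 0.2 / tot)

  expect_error(
    quadrant_buried_volume(s, 3, center = 1, z_target = 2,
                           xz_atom = c(0, 0, 5)),
    "degenerate frame"
  )
})

test_that("exact cone angle matches the one-atom closed form", {
  s <- mk(c("Rh", "P"), c(0, 0, 0, 2.28, 0, 0))
  got <- exact_cone_angle(s, 1, 2, radii_scale = 1.0)
  expect_equal(got$angle, 2 * asin(1.80 / 2.28) * 180 / pi,
               tolerance = 0.1 / 104)
  # axis points at the atom
  expect_equal(as.numeric(got$axis), c(1, 0, 0), tolerance = 1e-3)
})

test_that("exact cone angle matches a brute-force axis scan", {
  s <- mk(c("Rh", "P", "P", "C"),
          c(0, 0, 0, 1.8, 1.4, 0.2, 1.9, -1.3, -0.4, 2.6, 0.3, 1.1))
  got <- exact_cone_angle(s, 1, 2:4)$angle
  oracle <- bf_cone_angle(s, 1, 2:4, n_dirs = 1e6)
  expect_equal(got, oracle, tolerance = 0.1 / got)
  expect_lte(got, oracle + 1e-6) # optimizer must not exceed the scan
})

test_that("cone angle is monotone under containment and rotation-invariant", {
  s <- mk(c("Rh", "P", "P"), c(0, 0, 0, 2.3, 1.5, 0, 2.3, -1.5, 0))
  base <- exact_cone_angle(s, 1, 2:3)$angle
  # a small atom inside the cone leaves the angle unchanged
  s2 <- mk(c("Rh", "P", "P", "H"),
           c(0, 0, 0, 2.3, 1.5, 0, 2.3, -1.5, 0, 3.5, 0, 0))
  expect_equal(exact_cone_angle(s2, 1, 2:4)$angle, base, tolerance = 1e-4)
  rot <- random_rotation(9)
  s3 <- chiralcat:::rotate_structure(s, rot)
  expect_equal(exact_cone_angle(s3, 1, 2:3)$angle, base, tolerance = 1e-4)
  # engulfing sphere
  close <- mk(c("Rh", "P"), c(0, 0, 0, 1.0, 0, 0))
  expect_error(exact_cone_angle(close, 1, 2), "engulfs")
})

test_that("sterimol matches the single-atom closed form", {
  s <- mk(c("C", "H"), c(0, 0, 0, 1.09, 0, 0))
  got <- sterimol(s, 1, 2, 2, radii_scale = 1.10 / 1.20)
  expect_equal(got$L, 2.19, tolerance = 1e-9)
  expect_equal(got$B1, 1.10, tolerance = 1e-6)
  expect_equal(got$B5, 1.10, tolerance = 1e-9)
})

test_that("sterimol matches a 36000-direction brute-force oracle", {
  s <- mk(c("C", "C", "H", "Cl"),
          c(0, 0, 0, 1.52, 0.1, -0.2, 2.1, 1.0, 0.3, 2.4, -1.2, 0.8))
  got <- sterimol(s, 1, 2, 2:4)
  oracle <- bf_sterimol(s, 1, 2, 2:4, n_dirs = 36000)
  expect_equal(got$L, oracle$L, tolerance = 1e-9)
  expect_equal(got$B5, oracle$B5, tolerance = 1e-9)
  expect_equal(got$B1, oracle$B1, tolerance = 0.01 / oracle$B1)
})

test_that("B1 <= B5 on randomly generated substituents", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(3:7, 1)
    s <- xyz_structure("rand", c("C", sample(c("C", "H", "O", "F"), n,
                                             replace = TRUE)),
                       rbind(c(0, 0, 0),
                             cbind(runif(n, 0.8, 3), rnorm(n), rnorm(n))))
    st <- sterimol(s, 1, 2, 2:(n + 1))
    expect_lte(st$B1, st$B5 + 1e-9)
    expect_gt(st$L, 0)
  }
})

test_that("bite angle handles orthogonal, collinear and generic cases", {
  s <- mk(c("Rh", "P", "P"), c(0, 0, 0, 2, 0, 0, 0, 2, 0))
  expect_equal(bite_angle(s, 1, 2, 3), 90)
  s2 <- mk(c("Rh", "P", "P"), c(0, 0, 0, 2, 0, 0, -2, 0, 0))
  expect_equal(bite_angle(s2, 1, 2, 3), 180)
  # law of cosines on a generic triangle
  s3 <- mk(c("Rh", "P", "N"), c(0.3, -0.2, 0.5, 2.1, 0.8, -0.4,
                                -0.9, 2.2, 1.3))
  a <- atom_distance(s3, 1, 2)
  b <- atom_distance(s3, 1, 3)
  cc <- atom_distance(s3, 2, 3)
  expect_equal(bite_angle(s3, 1, 2, 3),
               acos((a^2 + b^2 - cc^2) / (2 * a * b)) * 180 / pi,
               tolerance = 1e-9)
  expect_error(bite_angle(mk(c("Rh", "P", "P"),
                             c(0, 0, 0, 0, 0, 0, 1, 0, 0)), 1, 2, 3),
               "coincident")
})

test_that("the diene dihedral is coplanar-zero and mirror-antisymmetric", {
  fx <- generate_complex_fixture(seed = 13)
  p <- partition_complex(fx$structure, build_graph(fx$structure))
  da <- assign_donor_labels(p, fx$sidecar_complex)
  d <- nbd_dihedral(fx$structure, p, da)
  mirror <- chiralcat:::reflect_structure(fx$structure)
  d_m <- nbd_dihedral(mirror, p, da)
  expect_equal(d_m, -d, tolerance = 1e-9)

  # coplanar four points give exactly 0 or 180
  p1 <- c(2, 1, 0); p2 <- c(0, 0, 0); p3 <- c(-2, 0.5, 0); p4 <- c(-4, 2, 0)
  d0 <- chiralcat:::dihedral_points(p1, p2, p3, p4)
  expect_true(abs(d0) < 1e-9 || abs(abs(d0) - 180) < 1e-9)

  # generic quadruple matches an independent vector-algebra evaluation
  q <- list(c(0.2, 1.4, -0.3), c(0, 0, 0), c(-1.1, 0.4, 0.8),
            c(-2.0, -0.7, 1.9))
  b1 <- q[[2]] - q[[1]]; b2 <- q[[3]] - q[[2]]; b3 <- q[[4]] - q[[3]]
  n1 <- pracma::cross(b1, b2); n2 <- pracma::cross(b2, b3)
  m1 <- pracma::cross(n1, b2 / sqrt(sum(b2^2)))
  ref <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  expect_equal(chiralcat:::dihedral_points(q[[1]], q[[2]], q[[3]], q[[4]]),
               ref, tolerance = 1e-6)
})

test_that("distance and centroid are Euclidean", {
  s <- mk(c("C", "C"), c(0, 0, 0, 3, 4, 0))
  expect_equal(atom_distance(s, 1, 2), 5)
  expect_equal(centroid(s, 1:2), c(1.5, 2, 0))
  set.seed(2)
  xyz <- matrix(rnorm(12), ncol = 3)
  s2 <- xyz_structure("r", rep("C", 4), xyz)
  expect_equal(atom_distance(s2, 1, 3), sqrt(sum((xyz[1, ] - xyz[3, ])^2)))
  expect_equal(centroid(s2, 1:4), colMeans(xyz))
})
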