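# The 34-descriptor catalyst schema and the featurization pipeline.

test_that("the schema registry has 34 descriptors, 15/8/11 by category", {
  schema <- catalyst_schema()
  expect_equal(nrow(schema), 34)
  counts <- table(schema$category)
  expect_equal(unname(counts[c("steric", "geometric", "electronic")]),
               c(15L, 8L, 11L), ignore_attr = TRUE)
  # anchored members
  expect_match(schema$description[schema$name == "S15"], "min donor")
  expect_match(schema$description[schema$name == "G4"], "metal - min donor")
  expect_match(schema$description[schema$name == "E5"], "metal")
  expect_match(schema$description[schema$name == "E7"],
               "min donor, free ligand")
  expect_match(schema$description[schema$name == "E10"],
               "max donor, free ligand")
})

test_that("featurization fills all 34 descriptors with sane values", {
  fx <- generate_complex_fixture(arm_bulk = 2, bite_angle_target = 92,
                                 seed = 21)
  row <- featurize_catalyst(fx$structure, fx$sidecar_complex,
                            fx$sidecar_free_ligand, grid_spacing = 0.1)
  expect_equal(names(row), c("ligand_id", catalyst_schema()$name))
  vals <- unlist(row[1, -1])
  expect_true(all(is.finite(vals)))
  svals <- unlist(row[1, paste0("S", 1:15)])
  expect_true(all(svals >= 0 & svals <= 100))
  expect_equal(row$G1, 92, tolerance = 1 / 92)
  # electronic anchors come straight from the sidecars
  da <- assign_donor_labels(
    partition_complex(fx$structure, build_graph(fx$structure)),
    fx$sidecar_complex)
  expect_equal(row$E5, unname(fx$sidecar_complex$nbo_charge["1"]))
  expect_equal(row$E4, unname(
    fx$sidecar_complex$lone_pair_occupancy[as.character(da$min_donor)]))
})

test_that("hand-computed geometry matches G1 and G4-G6", {
  fx <- generate_complex_fixture(bite_angle_target = 85, seed = 22)
  row <- featurize_catalyst(fx$structure, fx$sidecar_complex,
                            fx$sidecar_free_ligand, grid_spacing = 0.1)
  st <- fx$structure
  p <- partition_complex(st, build_graph(st))
  da <- assign_donor_labels(p, fx$sidecar_complex)
  expect_equal(row$G1, bite_angle(st, 1, da$min_donor, da$max_donor))
  expect_equal(row$G4, atom_distance(st, 1, da$min_donor))
  expect_equal(row$G5, atom_distance(st, 1, da$max_donor))
  expect_equal(row$G6, atom_distance(st, da$min_donor, da$max_donor))
  expect_equal(row$G4, 2.3, tolerance = 1e-6)
})

test_that("the mirror-image complex flips only the dihedral sign", {
  fx <- generate_complex_fixture(arm_bulk = 1, seed = 23)
  a <- featurize_catalyst(fx$structure, fx$sidecar_complex,
                          fx$sidecar_free_ligand, grid_spacing = 0.1)
  mirror <- chiralcat:::reflect_structure(fx$structure)
  b <- featurize_catalyst(mirror, fx$sidecar_complex,
                          fx$sidecar_free_ligand, grid_spacing = 0.1,
                          ligand_id = a$ligand_id)
  expect_equal(b$G3, -a$G3, tolerance = 1e-9)
  # the handed quadrant frame flips its y axis under reflection, so the
  # quadrant pairs swap: x+y+ <-> x+y-, x-y+ <-> x-y-
  expect_equal(b$S1, a$S3, tolerance = 0.3 / a$S3)
  expect_equal(b$S2, a$S4, tolerance = 0.3 / a$S4)
  expect_equal(b$S3, a$S1, tolerance = 0.3 / a$S1)
  expect_equal(b$S4, a$S2, tolerance = 0.3 / a$S2)
  same <- setdiff(catalyst_schema()$name, c("G3", paste0("S", 1:4)))
  svals <- paste0("S", 5:15)
  for (nm in setdiff(same, svals)) {
    expect_equal(b[[nm]], a[[nm]], tolerance = 1e-5, label = nm)
  }
  for (nm in svals) { # grid re-voxelisation jitter only
    expect_equal(b[[nm]], a[[nm]], tolerance = 0.3 / max(1, a[[nm]]),
                 label = nm)
  }
})

test_that("atom-order permutation does not change descriptor values", {
  fx <- generate_complex_fixture(seed = 24)
  st <- fx$structure
  a <- featurize_catalyst(st, fx$sidecar_complex, fx$sidecar_free_ligand,
                          grid_spacing = 0.1)
  set.seed(5)
  perm <- sample(n_atoms(st))
  inv <- order(perm)
  st2 <- xyz_structure(st$id, st$atoms$element[perm],
                       coords_matrix(st)[perm, ], charge = st$charge)
  remap <- function(sc) {
    names(sc$nbo_charge) <- as.character(inv[as.integer(
      names(sc$nbo_charge))])
    names(sc$lone_pair_occupancy) <- as.character(inv[as.integer(
      names(sc$lone_pair_occupancy))])
    sc
  }
  scx <- remap(fx$sidecar_complex)
  # free-ligand sidecar: recompute keys under the permuted extraction order
  p1 <- partition_complex(st, build_graph(st))
  p2 <- partition_complex(st2, build_graph(st2))
  m1 <- attr(extract_free_ligand(st, p1), "index_map")
  m2 <- attr(extract_free_ligand(st2, p2), "index_map")
  scf <- fx$sidecar_free_ligand
  old_complex <- m1$old[match(as.integer(names(scf$nbo_charge)), m1$new)]
  names(scf$nbo_charge) <- as.character(
    m2$new[match(inv[old_complex], m2$old)])
  old_complex <- m1$old[match(as.integer(names(scf$lone_pair_occupancy)),
                              m1$new)]
  names(scf$lone_pair_occupancy) <- as.character(
    m2$new[match(inv[old_complex], m2$old)])
  b <- featurize_catalyst(st2, scx, scf, grid_spacing = 0.1,
                          ligand_id = a$ligand_id)
  for (nm in catalyst_schema()$name) {
    expect_equal(b[[nm]], a[[nm]], tolerance = 1e-5, label = nm)
  }
})

test_that("featurize_library maps a manifest to a stable table", {
  dir <- withr::local_tempdir()
  rows <- list()
  for (k in 1:3) {
    fx <- generate_complex_fixture(arm_bulk = 1 + k %% 2,
                                   bite_angle_target = 80 + 5 * k,
                                   seed = 30 + k)
    write_xyz(fx$structure, file.path(dir, sprintf("L%d.xyz", k)))
    write_sidecar(fx$sidecar_complex,
                  file.path(dir, sprintf("L%d.complex.json", k)))
    write_sidecar(fx$sidecar_free_ligand,
                  file.path(dir, sprintf("L%d.free.json", k)))
    rows[[k]] <- tibble::tibble(
      ligand_id = sprintf("L%d", k),
      xyz = file.path(dir, sprintf("L%d.xyz", k)),
      sidecar_complex = file.path(dir, sprintf("L%d.complex.json", k)),
      sidecar_free_ligand = file.path(dir, sprintf("L%d.free.json", k))
    )
  }
  manifest <- dplyr::bind_rows(rows)
  t1 <- featurize_library(manifest, grid_spacing = 0.1)
  expect_equal(dim(t1), c(3, 35))
  expect_equal(names(t1), c("ligand_id", catalyst_schema()$name))
  # rerun is identical
  t2 <- featurize_library(manifest, grid_spacing = 0.1)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # a broken entry is reported, not fatal
  broken <- dplyr::bind_rows(
    manifest,
    tibble::tibble(ligand_id = "L9", xyz = "missing.xyz",
                   sidecar_complex = "x.json", sidecar_free_ligand = "y.json")
  )
  expect_message(t3 <- featurize_library(broken, grid_spacing = 0.1),
                 "failed")
  expect_equal(nrow(t3), 3)
  expect_equal(attr(t3, "failures")$ligand_id, "L9")
})
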