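# Bond perception, complex partitioning and donor labelling.

test_that("covalent-radii bond rule matches the bundled table", {
  h2 <- mk(c("H", "H"), c(0, 0, 0, 0.74, 0, 0))
  g <- build_graph(h2)
  expect_equal(nrow(g$edges), 1) # 0.74 <= 1.2 * (0.31 + 0.31)

  far <- mk(c("C", "C"), c(0, 0, 0, 10, 0, 0))
  expect_equal(nrow(build_graph(far)$edges), 0)
})

test_that("a two-fragment structure yields two components", {
  st <- mk(c("C", "H", "O", "H"),
           c(0, 0, 0, 1.09, 0, 0, 8, 0, 0, 8.96, 0, 0))
  memb <- chiralcat:::graph_components(build_graph(st))
  expect_equal(length(unique(memb)), 2)
  expect_equal(memb[1], memb[2])
  expect_equal(memb[3], memb[4])
})

test_that("partitioning recovers the known atom roles of a toy complex", {
  fx <- generate_complex_fixture(arm_bulk = 2, bite_angle_target = 95,
                                 seed = 3)
  p <- partition_complex(fx$structure, build_graph(fx$structure))
  expect_equal(p$metal_index, fx$bookkeeping$metal)
  expect_equal(p$donor_indices, sort(fx$bookkeeping$donors))
  expect_equal(p$ligand_atoms, sort(fx$bookkeeping$ligand_atoms))
  expect_equal(p$auxiliary_atoms, sort(fx$bookkeeping$auxiliary_atoms))
  # disjoint and exhaustive
  all_atoms <- sort(c(p$metal_index, p$ligand_atoms, p$auxiliary_atoms))
  expect_equal(all_atoms, seq_len(n_atoms(fx$structure)))
})

test_that("a monophosphine gives a single donor; no metal is an error", {
  st <- mk(c("Rh", "P", "C", "H", "H", "H"),
           c(0, 0, 0, 2.3, 0, 0, 4.1, 0, 0,
             4.5, 1, 0, 4.5, -0.9, 0.3, 4.5, -0.2, -1))
  p <- partition_complex(st, build_graph(st))
  expect_equal(p$donor_indices, 2L)
  expect_equal(length(p$auxiliary_atoms), 0)

  no_metal <- mk(c("P", "C"), c(0, 0, 0, 1.85, 0, 0))
  expect_error(partition_complex(no_metal, build_graph(no_metal)),
               "exactly one Rh")
})

test_that("donor labels follow charge, with index tie-breaking", {
  fx <- generate_complex_fixture(seed = 4)
  p <- partition_complex(fx$structure, build_graph(fx$structure))

  sc <- electronic_sidecar("x", "complex", 3,
                           nbo_charge = c("1" = 0, "2" = 0.85, "3" = 0.62))
  da <- assign_donor_labels(p, sc)
  expect_equal(da$max_donor, 2L)
  expect_equal(da$min_donor, 3L)

  tie <- electronic_sidecar("x", "complex", 3,
                            nbo_charge = c("2" = 0.7, "3" = 0.7))
  da_tie <- assign_donor_labels(p, tie)
  expect_equal(da_tie$min_donor, 2L)
  expect_equal(da_tie$max_donor, 2L)

  missing <- electronic_sidecar("x", "complex", 3,
                                nbo_charge = c("2" = 0.7))
  expect_error(assign_donor_labels(p, missing), "donor atom")
})

test_that("a P,N ligand puts the nitrogen at the min-donor role", {
  fx <- generate_complex_fixture(seed = 6, donor_elements = c("P", "N"))
  p <- partition_complex(fx$structure, build_graph(fx$structure))
  da <- assign_donor_labels(p, fx$sidecar_complex)
  expect_equal(fx$structure$atoms$element[da$min_donor], "N")
  expect_equal(fx$structure$atoms$element[da$max_donor], "P")
})

test_that("free-ligand extraction is a coordinate-preserving bijection", {
  fx <- generate_complex_fixture(arm_bulk = 3, seed = 8)
  p <- partition_complex(fx$structure, build_graph(fx$structure))
  free <- extract_free_ligand(fx$structure, p)
  imap <- attr(free, "index_map")
  expect_equal(n_atoms(free), length(p$ligand_atoms))
  expect_equal(sort(imap$new), seq_len(nrow(imap)))
  expect_equal(anyDuplicated(imap$old), 0)
  # coordinates unchanged under the mapping
  expect_equal(coords_matrix(free)[imap$new, ],
               coords_matrix(fx$structure)[imap$old, ])
  # donor indices remap onto donor elements
  free_donors <- imap$new[match(p$donor_indices, imap$old)]
  expect_true(all(free$atoms$element[free_donors] %in% c("P", "N")))
})

test_that("donor labelling is invariant under atom-order permutation", {
  fx <- generate_complex_fixture(seed = 9)
  st <- fx$structure
  set.seed(1)
  perm <- sample(n_atoms(st))
  st2 <- xyz_structure("perm", st$atoms$element[perm],
                       coords_matrix(st)[perm, ], charge = st$charge)
  inv <- order(perm)
  sc2 <- fx$sidecar_complex
  names(sc2$nbo_charge) <- as.character(inv[as.integer(
    names(sc2$nbo_charge))])
  names(sc2$lone_pair_occupancy) <- as.character(inv[as.integer(
    names(sc2$lone_pair_occupancy))])
  p1 <- partition_complex(st, build_graph(st))
  p2 <- partition_complex(st2, build_graph(st2))
  d1 <- assign_donor_labels(p1, fx$sidecar_complex)
  d2 <- assign_donor_labels(p2, sc2)
  expect_equal(inv[d1$min_donor], d2$min_donor)
  expect_equal(inv[d1$max_donor], d2$max_donor)
})
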