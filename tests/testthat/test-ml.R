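# The modeling harness: design matrices, splits, metrics, enumeration,
# the forest runner and the Monte-Carlo subset study.

ml_fixture <- function(seed = 1, n_ligands = 48,
                       signal_mode = "identity_driven") {
  desc <- generate_descriptor_table(n_ligands, seed = seed)
  spec <- outcome_spec(n_ligands = n_ligands, signal_mode = signal_mode,
                       seed = seed)
  records <- select_modeling_subset(generate_outcomes(spec, desc))
  tables <- build_feature_tables(records$ligand_id, records$substrate_id,
                                 descriptors = desc, seed = seed)
  list(records = records, tables = tables, desc = desc)
}

test_that("design matrices have the expected widths and provenance", {
  fx <- ml_fixture(n_ligands = 24)
  sub_fp <- tibble::tibble(substrate_id = paste0("SM", 1:5))
  for (k in 1:18) sub_fp[[sprintf("f%02d", k)]] <- rnorm(5)
  fx$tables$substrate$dft_fp <- sub_fp

  dm <- build_design_matrix(fx$records, fx$tables, "dft", "dft_fp",
                            "full_ood")
  expect_equal(ncol(dm$X), 34 + 18)
  expect_true(all(startsWith(colnames(dm$X)[1:34], "lig_")))
  expect_true(all(startsWith(colnames(dm$X)[35:52], "sub_")))

  dm2 <- build_design_matrix(fx$records, fx$tables, "ohe", "ohe",
                             "full_ood")
  expect_equal(ncol(dm2$X), 24 + 5)
  expect_true(all(rowSums(dm2$X[, 1:24]) == 1))

  dm3 <- build_design_matrix(fx$records, fx$tables, "dft",
                             mode = "in_domain")
  expect_equal(ncol(dm3$X), 34)

  bad <- fx$records
  bad$ligand_id[1] <- "L999"
  expect_error(build_design_matrix(bad, fx$tables, "dft", "ohe",
                                   "full_ood"), "L999")
})

test_that("splits respect domain boundaries and published sizes", {
  fx <- ml_fixture(n_ligands = 192)
  rec <- fx$records
  # fully out-of-domain, case 1: all 192 target catalysts in test
  s1 <- split_experiment(rec, "full_ood", "SM3", c("SM1", "SM2"))
  expect_equal(length(s1$test), 192)
  expect_equal(length(s1$train), 384)
  expect_setequal(unique(rec$substrate_id[s1$train]), c("SM1", "SM2"))

  # partially out-of-domain: half the target catalysts move to training
  s2 <- split_experiment(rec, "partial_ood", "SM3", c("SM1", "SM2"),
                         split_seed = 2)
  expect_equal(length(s2$test), 96)
  expect_equal(length(s2$train), 384 + 96)
  leak <- intersect(rec$ligand_id[intersect(
    s2$train, which(rec$substrate_id == "SM3"))],
    rec$ligand_id[s2$test])
  expect_equal(length(leak), 0)

  # in-domain 80:20 with a floor rule on the training side
  s3 <- split_experiment(rec, "in_domain", "SM1", split_seed = 3)
  expect_equal(length(s3$train), 153)
  expect_equal(length(s3$test), 39)
  expect_equal(length(intersect(rec$ligand_id[s3$train],
                                rec$ligand_id[s3$test])), 0)
  # seed determinism
  s3b <- split_experiment(rec, "in_domain", "SM1", split_seed = 3)
  expect_identical(s3, s3b)
})

test_that("balanced accuracy is the mean of per-class recalls", {
  expect_equal(balanced_accuracy(c(1, 1, 1, 0), c(1, 1, 0, 0)),
               (2 / 3 + 1) / 2)
  expect_equal(balanced_accuracy(c("a", "b"), c("a", "b")), 1)
  expect_equal(balanced_accuracy(c("a", "a", "b", "b"),
                                 c("a", "a", "a", "a")), 0.5)
})

test_that("the experiment grids have the published sizes", {
  expect_equal(nrow(enumerate_experiments("full_ood")), 168)
  expect_equal(nrow(enumerate_experiments("partial_ood")), 504)
  expect_equal(nrow(enumerate_experiments("in_domain")), 90)
  total <- nrow(enumerate_experiments("full_ood")) +
    nrow(enumerate_experiments("partial_ood")) +
    nrow(enumerate_experiments("in_domain"))
  expect_gte(total, 700)
  # random-descriptor controls enumerate separately
  ctrl <- enumerate_experiments("full_ood", ligand_reps = "random")
  expect_equal(nrow(ctrl), 56)
})

test_that("the forest runner learns a separable task to the ceiling", {
  fx <- ml_fixture(n_ligands = 48)
  rec <- fx$records
  # plant a wide-margin signal in one descriptor column, same per ligand
  s1 <- fx$desc$S1[match(rec$ligand_id, fx$desc$ligand_id)]
  rec$conversion <- ifelse(s1 > 0, 0.95, 0.05)
  res <- run_experiment(rec, fx$tables, "full_ood",
                        target = "conversion", ligand_rep = "dft",
                        substrate_rep = "ohe", case_id = 1,
                        tune = FALSE, seed = 1)
  expect_s3_class(res, "chiralcat_result")
  expect_equal(res$metric, 1.0)
  expect_equal(sum(res$importances$importance), 1, tolerance = 1e-9)
  expect_equal(res$n_test, 192) # 48 catalysts x 4 replicate wells
})

test_that("degenerate single-class training targets are an error", {
  fx <- ml_fixture(n_ligands = 24)
  rec <- fx$records[fx$records$substrate_id == "SM1", ]
  rec$conversion <- 1
  expect_error(
    run_experiment(rec, fx$tables, "in_domain", target = "conversion",
                   ligand_rep = "dft", substrate = "SM1", threshold = 0.5,
                   tune = FALSE),
    "degenerate"
  )
})

test_that("importances split between duplicated feature columns", {
  fx <- ml_fixture(n_ligands = 48, signal_mode = "descriptor_driven")
  desc_dup <- fx$desc
  desc_dup$S1_copy <- desc_dup$S1 # perfectly correlated duplicate
  tables <- build_feature_tables(fx$records$ligand_id,
                                 fx$records$substrate_id,
                                 descriptors = desc_dup, seed = 1)
  res <- run_experiment(fx$records, tables, "in_domain",
                        target = "selectivity", ligand_rep = "dft",
                        substrate = "SM1", tune = FALSE, seed = 2)
  imp <- res$importances
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  a <- imp$importance[imp$feature == "lig_S1"]
  b <- imp$importance[imp$feature == "lig_S1_copy"]
  # both correlated copies receive a share of the credit
  expect_gt(a, 0)
  expect_gt(b, 0)
})

test_that("tuning scores the grid and returns the winning parameters", {
  fx <- ml_fixture(n_ligands = 32, signal_mode = "descriptor_driven")
  grid <- tidyr::expand_grid(num_trees = 50L, max_depth = c(3L, 10L),
                             min_node_size = 1L)
  res <- run_experiment(fx$records, fx$tables, "in_domain",
                        target = "conversion", ligand_rep = "dft",
                        substrate = "SM1", grid = grid, k_folds = 3,
                        seed = 3)
  expect_true(res$best_params$max_depth %in% c(3L, 10L))
  expect_equal(glance(res)$value, res$metric)
  expect_equal(nrow(tidy(res)), 34)
})

test_that("the Monte-Carlo subset study is reproducible and logs splits", {
  fx <- ml_fixture(n_ligands = 48)
  rec <- fx$records[fx$records$substrate_id == "SM1", ]
  mc1 <- monte_carlo_subsets(rec, fx$desc, fractions = c(0.5, 0.25),
                             n_splits = 8, seed = 9)
  mc2 <- monte_carlo_subsets(rec, fx$desc, fractions = c(0.5, 0.25),
                             n_splits = 8, seed = 9)
  expect_identical(mc1$results, mc2$results)
  expect_identical(mc1$memberships, mc2$memberships)
  expect_equal(nrow(mc1$results), 16)
  # 24 sampled catalysts -> 19 in training, 4 replicate wells each
  expect_equal(unique(mc1$results$n_train[mc1$results$fraction == 0.5]),
               floor(0.8 * 24) * 4)
  # a fraction too small to test is skipped with a warning
  expect_warning(
    mc3 <- monte_carlo_subsets(rec, fx$desc, fractions = c(0.05),
                               n_splits = 2, seed = 1),
    "skipped"
  )
  expect_equal(nrow(mc3$results), 0)
})
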