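# The modeling benchmark: seven fully out-of-domain cases, partially
# out-of-domain and in-domain experiments with a random-forest learner,
# balanced-accuracy / R2 metrics, Gini importances, and the Monte-Carlo
# subset study that exposes chance correlation on tiny test sets.

#' The seven out-of-domain cases
#'
#' Cases 1-3 predict one of the three mutually correlated substrates from
#' the other two; cases 4-6 add the two unrelated substrates to the
#' training set; case 7 predicts the unrelated SM4 from SM3 and SM5.
#'
#' @return Tibble with `case_id`, `target_substrate` and a
#'   `training_substrates` list-column.
#' @export
case_specs <- function() {
  tibble::tibble(
    case_id = 1:7,
    target_substrate = c("SM3", "SM2", "SM1", "SM3", "SM2", "SM1", "SM4"),
    training_substrates = list(
      c("SM1", "SM2"), c("SM1", "SM3"), c("SM2", "SM3"),
      c("SM1", "SM2", "SM4", "SM5"), c("SM1", "SM3", "SM4", "SM5"),
      c("SM2", "SM3", "SM4", "SM5"), c("SM3", "SM5")
    )
  )
}

#' Enumerate the benchmark experiments
#'
#' Fully out-of-domain: 7 cases x 2 targets x 3 ligand representations
#' (dft, ecfp, ohe) x 4 substrate representations = 168.  Partially
#' out-of-domain: the same crossed with 3 split seeds = 504.  In-domain:
#' 5 substrates x 3 ligand representations x 2 targets x 3 seeds = 90
#' (catalyst features only).  Random-descriptor controls are enumerated
#' separately via `ligand_reps = "random"`.
#'
#' @param mode One of `"full_ood"`, `"partial_ood"`, `"in_domain"`.
#' @param ligand_reps Ligand representations to cross (default the three
#'   non-random ones).
#' @param split_seeds Seeds for the random splits (partial/in-domain).
#' @return Tibble of experiment specifications, one row per model.
#' @export
enumerate_experiments <- function(mode = c("full_ood", "partial_ood",
                                           "in_domain"),
                                  ligand_reps = c("dft", "ecfp", "ohe"),
                                  split_seeds = 1:3) {
  mode <- match.arg(mode)
  targets <- c("conversion", "selectivity")
  substrate_reps <- c("dft_fp", "smiles_fp", "ecfp", "ohe")
  if (mode == "full_ood") {
    out <- tidyr::expand_grid(
      mode = mode, case_id = 1:7, target = targets,
      ligand_rep = ligand_reps, substrate_rep = substrate_reps,
      split_seed = NA_integer_
    )
  } else if (mode == "partial_ood") {
    out <- tidyr::expand_grid(
      mode = mode, case_id = 1:7, target = targets,
      ligand_rep = ligand_reps, substrate_rep = substrate_reps,
      split_seed = split_seeds
    )
  } else {
    out <- tidyr::expand_grid(
      mode = mode, substrate = paste0("SM", 1:5), target = targets,
      ligand_rep = ligand_reps, substrate_rep = NA_character_,
      split_seed = split_seeds
    )
  }
  out
}

#' Assemble feature tables for the benchmark
#'
#' Builds the per-id feature tables the design matrices join against.
#' Always includes one-hot and (seeded) random-descriptor ligand tables;
#' a descriptor table adds the `dft` representation; ligand SMILES add
#' `ecfp`.  Substrate tables: one-hot always; SMILES add `ecfp`,
#' `smiles_fp` (fingerprint of the embedded conformer) and, unless
#' distinct geometries are supplied, `dft_fp` falls back to the same
#' embedded-conformer fingerprint.
#'
#' @param ligand_ids Character vector of all ligand ids.
#' @param substrate_ids Character vector of all substrate ids.
#' @param descriptors Optional catalyst descriptor table (`ligand_id` +
#'   schema columns).
#' @param ligand_smiles Optional tibble `ligand_id`, `smiles`.
#' @param substrate_smiles Optional tibble `substrate_id`, `smiles`.
#' @param substrate_structures Optional named list of [xyz_structure()]s
#'   for the `dft_fp` substrate fingerprint.
#' @param seed Seed for the random-descriptor control.
#' @return List with `ligand` and `substrate` sublists of feature tibbles,
#'   each keyed by its first column.
#' @export
build_feature_tables <- function(ligand_ids, substrate_ids,
                                 descriptors = NULL, ligand_smiles = NULL,
                                 substrate_smiles = NULL,
                                 substrate_structures = NULL, seed = 1) {
  lig <- list(
    ohe = dplyr::rename(one_hot(sort(unique(ligand_ids))),
                        ligand_id = "id"),
    random = dplyr::rename(random_descriptors(ligand_ids, seed = seed),
                           ligand_id = "id")
  )
  if (!is.null(descriptors)) lig$dft <- descriptors
  if (!is.null(ligand_smiles)) {
    fp <- circular_fingerprint(ligand_smiles$smiles)
    lig$ecfp <- dplyr::bind_cols(
      tibble::tibble(ligand_id = ligand_smiles$ligand_id),
      fp[, -1]
    )
  }
  sub <- list(
    ohe = dplyr::rename(one_hot(sort(unique(substrate_ids))),
                        substrate_id = "id")
  )
  if (!is.null(substrate_smiles)) {
    fp <- circular_fingerprint(substrate_smiles$smiles)
    sub$ecfp <- dplyr::bind_cols(
      tibble::tibble(substrate_id = substrate_smiles$substrate_id),
      fp[, -1]
    )
    embedded <- lapply(seq_len(nrow(substrate_smiles)), function(k) {
      embed_from_smiles(substrate_smiles$smiles[[k]], seed = seed,
                        id = substrate_smiles$substrate_id[[k]])
    })
    names(embedded) <- substrate_smiles$substrate_id
    fp18 <- dplyr::bind_rows(lapply(embedded, function(st) {
      substrate_fingerprint(st, locate_olefin(st))
    }))
    sub$smiles_fp <- dplyr::bind_cols(
      tibble::tibble(substrate_id = substrate_smiles$substrate_id), fp18)
    sub$dft_fp <- sub$smiles_fp
  }
  if (!is.null(substrate_structures)) {
    fp18 <- dplyr::bind_rows(lapply(substrate_structures, function(st) {
      substrate_fingerprint(st, locate_olefin(st))
    }))
    sub$dft_fp <- dplyr::bind_cols(
      tibble::tibble(substrate_id = names(substrate_structures)), fp18)
  }
  list(ligand = lig, substrate = sub)
}

feature_block <- function(tbl, ids, key, prefix) {
  idx <- match(ids, tbl[[key]])
  if (anyNA(idx)) {
    stop("id(s) missing from the ", prefix, " feature table: ",
         paste(unique(ids[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(tbl[idx, -match(key, names(tbl)), drop = FALSE])
  colnames(X) <- paste0(prefix, "_", colnames(X))
  X
}

#' Build the design matrix for one experiment
#'
#' Out-of-domain rows concatenate ligand and substrate features; in-domain
#' rows use ligand (catalyst) features only.  Column names carry a
#' `lig_` / `sub_` provenance prefix.
#'
#' @param records HTE records (one row per well).
#' @param tables A [build_feature_tables()] result.
#' @param ligand_rep,substrate_rep Representation names.
#' @param mode `"full_ood"`, `"partial_ood"` or `"in_domain"`.
#' @return List with `X` (numeric matrix) and `records`.
#' @export
build_design_matrix <- function(records, tables, ligand_rep,
                                substrate_rep = NULL,
                                mode = "full_ood") {
  lt <- tables$ligand[[ligand_rep]]
  if (is.null(lt)) stop("unknown ligand representation: ", ligand_rep,
                        call. = FALSE)
  X <- feature_block(lt, records$ligand_id, "ligand_id", "lig")
  if (mode != "in_domain") {
    st <- tables$substrate[[substrate_rep]]
    if (is.null(st)) stop("unknown substrate representation: ",
                          substrate_rep, call. = FALSE)
    X <- cbind(X, feature_block(st, records$substrate_id, "substrate_id",
                                "sub"))
  }
  list(X = X, records = records)
}

#' Train/test split for one experiment
#'
#' Fully out-of-domain: train on all training-substrate rows, test on all
#' target-substrate rows.  Partially out-of-domain: additionally move a
#' seed-deterministic random half of the target-substrate catalysts into
#' training; test on the other half.  In-domain: 80:20 catalyst split
#' (train size is `floor(0.8 n)`).  In every mode no target-substrate
#' catalyst appears on both sides; this is asserted.
#'
#' @param records HTE records.
#' @param mode Split mode.
#' @param target_substrate Target substrate id.
#' @param training_substrates Training substrate ids (out-of-domain).
#' @param split_seed Seed for the random half / 80:20 split.
#' @return List with integer row indices `train` and `test`.
#' @export
split_experiment <- function(records, mode, target_substrate,
                             training_substrates = NULL, split_seed = 1) {
  target_rows <- which(records$substrate_id == target_substrate)
  if (mode == "in_domain") {
    cats <- sort(unique(records$ligand_id[target_rows]))
    set.seed(split_seed)
    perm <- sample(cats)
    n_train <- floor(0.8 * length(cats))
    train_cats <- perm[seq_len(n_train)]
    train <- target_rows[records$ligand_id[target_rows] %in% train_cats]
    test <- setdiff(target_rows, train)
  } else {
    train <- which(records$substrate_id %in% training_substrates)
    if (mode == "partial_ood") {
      cats <- sort(unique(records$ligand_id[target_rows]))
      set.seed(split_seed)
      half <- sample(cats, floor(length(cats) / 2))
      train <- c(train,
                 target_rows[records$ligand_id[target_rows] %in% half])
      test <- target_rows[!(records$ligand_id[target_rows] %in% half)]
    } else {
      test <- target_rows
    }
  }
  overlap <- intersect(records$ligand_id[intersect(train, target_rows)],
                       records$ligand_id[test])
  stopifnot("target-substrate catalyst leaks into both train and test" =
              length(overlap) == 0)
  list(train = sort(train), test = sort(test))
}

#' Balanced accuracy
#'
#' Mean of the per-class recalls over the classes present in `y_true`.
#'
#' @param y_true,y_pred Factors or vectors of class labels.
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' balanced_accuracy(c(1, 1, 1, 0), c(1, 1, 0, 0)) # (2/3 + 1)/2
balanced_accuracy <- function(y_true, y_pred) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  recalls <- vapply(unique(y_true), function(cl) {
    mean(y_pred[y_true == cl] == cl)
  }, numeric(1))
  mean(recalls)
}

r_squared <- function(y_true, y_pred) {
  1 - sum((y_true - y_pred)^2) / sum((y_true - mean(y_true))^2)
}

#' Default random-forest tuning grid
#'
#' @param unlimited_depth Use unbounded trees (the one-hot convention:
#'   nodes expand until all leaves are pure).
#' @return Tibble of `num_trees`, `max_depth` (0 = unlimited),
#'   `min_node_size` combinations.
#' @export
default_rf_grid <- function(unlimited_depth = FALSE) {
  tidyr::expand_grid(
    num_trees = c(100L, 300L),
    max_depth = if (unlimited_depth) 0L else c(3L, 5L, 10L),
    min_node_size = c(1L, 3L)
  )
}

fit_rf <- function(X, y, params, classification, seed) {
  ranger::ranger(
    x = X, y = y,
    num.trees = params$num_trees,
    max.depth = params$max_depth,
    min.node.size = params$min_node_size,
    classification = classification,
    importance = "impurity",
    seed = seed,
    num.threads = 1
  )
}

cv_score <- function(X, y, params, classification, k_folds, seed) {
  n <- length(y)
  set.seed(seed)
  fold <- sample(rep(seq_len(k_folds), length.out = n))
  scores <- vapply(seq_len(k_folds), function(f) {
    tr <- fold != f
    if (classification && length(unique(y[tr])) < 2) return(NA_real_)
    fit <- fit_rf(X[tr, , drop = FALSE], y[tr], params, classification,
                  seed)
    pred <- stats::predict(fit, X[!tr, , drop = FALSE])$predictions
    if (classification) balanced_accuracy(y[!tr], pred)
    else r_squared(y[!tr], pred)
  }, numeric(1))
  mean(scores, na.rm = TRUE)
}

#' Run one benchmark experiment
#'
#' Derives the target (conversion class at the requested threshold, or ddG
#' computed from ee at each well's temperature), splits by
#' [split_experiment()], optionally grid-searches the forest by k-fold
#' cross-validation on the training rows (balanced accuracy for
#' classification, R2 for regression), refits on the full training set and
#' evaluates on the held-out rows.  One-hot ligand features follow the
#' unlimited-depth convention.
#'
#' @param records HTE records (typically the 960-point modeling subset).
#' @param tables A [build_feature_tables()] result.
#' @param mode,target,ligand_rep,substrate_rep,case_id,substrate,split_seed
#'   Experiment coordinates; out-of-domain modes take `case_id` (see
#'   [case_specs()]), in-domain takes `substrate`.
#' @param threshold Conversion class boundary for out-of-domain runs
#'   (default 0.8); in-domain runs use the per-substrate median.
#' @param tune Grid-search the forest (default TRUE); FALSE fits one
#'   forest with 300 trees (depth 10, or unlimited for one-hot).
#' @param k_folds Cross-validation folds (default 5).
#' @param grid Hyperparameter grid; defaults to [default_rf_grid()].
#' @param seed RNG seed for fold assignment and the forests.
#' @return A `chiralcat_result` with the test metric, per-class recalls,
#'   normalized Gini importances and the winning hyperparameters.
#' @export
run_experiment <- function(records, tables, mode, target = "conversion",
                           ligand_rep = "dft", substrate_rep = "ohe",
                           case_id = NULL, substrate = NULL,
                           split_seed = 1, threshold = 0.8, tune = TRUE,
                           k_folds = 5, grid = NULL, seed = 1) {
  stopifnot(mode %in% c("full_ood", "partial_ood", "in_domain"),
            target %in% c("conversion", "selectivity"))
  if (mode == "in_domain") {
    stopifnot(!is.null(substrate))
    records <- records[records$substrate_id == substrate, ]
    target_substrate <- substrate
    training_substrates <- NULL
  } else {
    cs <- case_specs()[case_specs()$case_id == case_id, ]
    stopifnot(nrow(cs) == 1)
    target_substrate <- cs$target_substrate
    training_substrates <- cs$training_substrates[[1]]
    keep <- records$substrate_id %in% c(target_substrate,
                                        training_substrates)
    records <- records[keep, ]
  }

  classification <- target == "conversion"
  if (classification) {
    thr <- if (mode == "in_domain") {
      stats::median(records$conversion)
    } else {
      threshold
    }
    y <- label_conversion(records$conversion, thr)
  } else {
    y <- ee_to_ddg(records$ee, records$temperature)
    thr <- NA_real_
  }

  dm <- build_design_matrix(records, tables, ligand_rep, substrate_rep,
                            mode)
  idx <- split_experiment(records, mode, target_substrate,
                          training_substrates, split_seed)
  X_tr <- dm$X[idx$train, , drop = FALSE]
  y_tr <- y[idx$train]
  if (classification && length(unique(as.character(y_tr))) < 2) {
    stop("degenerate classification task: a single class in training",
         call. = FALSE)
  }

  if (is.null(grid)) grid <- default_rf_grid(ligand_rep == "ohe")
  if (!tune) {
    # untuned default: 300 trees, deepest gridded depth, minimal leaves
    grid <- tibble::tibble(
      num_trees = 300L,
      max_depth = if (ligand_rep == "ohe") 0L else max(grid$max_depth),
      min_node_size = 1L
    )
  }
  best <- grid[1, ]
  if (nrow(grid) > 1) {
    cv <- vapply(seq_len(nrow(grid)), function(g) {
      cv_score(X_tr, y_tr, grid[g, ], classification, k_folds, seed)
    }, numeric(1))
    best <- grid[which.max(cv), ]
  }

  fit <- fit_rf(X_tr, y_tr, best, classification, seed)
  pred <- stats::predict(fit, dm$X[idx$test, , drop = FALSE])$predictions
  y_te <- y[idx$test]
  if (classification) {
    metric <- balanced_accuracy(y_te, pred)
    metric_name <- "balanced_accuracy"
    recalls <- vapply(levels(y_te), function(cl) {
      if (!any(y_te == cl)) return(NA_real_)
      mean(pred[y_te == cl] == cl)
    }, numeric(1))
  } else {
    metric <- r_squared(y_te, pred)
    metric_name <- "r_squared"
    recalls <- NULL
  }
  imp <- fit$variable.importance
  imp <- if (sum(imp) > 0) imp / sum(imp) else imp
  spec <- list(mode = mode, target = target, ligand_rep = ligand_rep,
               substrate_rep = if (mode == "in_domain") NA_character_
                               else substrate_rep,
               case_id = case_id, substrate = substrate,
               split_seed = split_seed, threshold = thr, seed = seed)
  structure(
    list(
      spec = spec,
      metric = metric,
      metric_name = metric_name,
      per_class_recall = recalls,
      importances = tibble::tibble(feature = names(imp),
                                   importance = unname(imp)),
      best_params = best,
      n_train = length(idx$train),
      n_test = length(idx$test),
      fingerprint = rlang::hash(list(spec, best, metric, unname(imp)))
    ),
    class = "chiralcat_result"
  )
}

#' @export
print.chiralcat_result <- function(x, ...) {
  cat(sprintf(
    "<chiralcat_result %s/%s: %s = %.3f (train %d, test %d)>\n",
    x$spec$mode, x$spec$target, x$metric_name, x$metric, x$n_train,
    x$n_test
  ))
  invisible(x)
}

#' Monte-Carlo catalyst-subset study
#'
#' For each catalyst fraction, repeatedly samples that share of the
#' catalysts, splits the sample 80:20, fits a regression forest on the
#' supplied features, and records the test R2.  On tiny fractions the
#' maximum over many splits rises far above the full-data median even when
#' there is no real signal: the chance-correlation trap this study is
#' designed to expose.
#'
#' @param records In-domain HTE records of a single substrate.
#' @param features Feature table (`ligand_id` + numeric columns).
#' @param fractions Catalyst fractions (default 0.9 down to 0.1).
#' @param n_splits Random splits per fraction (default 1000).
#' @param seed RNG seed; with the returned membership log it reproduces
#'   every split exactly.
#' @param num_trees Trees per forest (default 100, untuned by design).
#' @return List with `results` (tibble: `fraction`, `split`, `r2`,
#'   `n_train`, `n_test`) and `memberships` (list of per-split training
#'   catalyst id vectors, named `fraction/split`).
#' @export
monte_carlo_subsets <- function(records, features,
                                fractions = seq(0.9, 0.1, by = -0.1),
                                n_splits = 1000, seed = 1,
                                num_trees = 100) {
  stopifnot(length(unique(records$substrate_id)) == 1)
  y_all <- ee_to_ddg(records$ee, records$temperature)
  X_all <- feature_block(features, records$ligand_id, "ligand_id", "lig")
  cats <- sort(unique(records$ligand_id))
  set.seed(seed)
  out <- list()
  memberships <- list()
  for (fr in fractions) {
    n_cat <- round(fr * length(cats))
    n_train <- floor(0.8 * n_cat)
    n_test <- n_cat - n_train
    if (n_test < 1 || n_train < 2) {
      warning(sprintf("fraction %.2f leaves no usable test set; skipped",
                      fr), call. = FALSE)
      next
    }
    for (s in seq_len(n_splits)) {
      pick <- sample(cats, n_cat)
      tr_cats <- pick[seq_len(n_train)]
      te_cats <- pick[(n_train + 1):n_cat]
      tr <- which(records$ligand_id %in% tr_cats)
      te <- which(records$ligand_id %in% te_cats)
      fit <- ranger::ranger(x = X_all[tr, , drop = FALSE], y = y_all[tr],
                            num.trees = num_trees, seed = seed,
                            num.threads = 1)
      pred <- stats::predict(fit, X_all[te, , drop = FALSE])$predictions
      out[[length(out) + 1]] <- tibble::tibble(
        fraction = fr, split = s, r2 = r_squared(y_all[te], pred),
        n_train = length(tr), n_test = length(te)
      )
      memberships[[sprintf("%.1f/%d", fr, s)]] <- tr_cats
    }
  }
  list(results = dplyr::bind_rows(out), memberships = memberships)
}
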