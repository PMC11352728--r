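# broom-style tidiers for fitted benchmark results and PCA maps.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a benchmark result
#'
#' @param x A `chiralcat_result` from [run_experiment()].
#' @param ... Unused.
#' @return The normalized feature importances as a tibble (`feature`,
#'   `importance`), sorted decreasing.
#' @exportS3Method generics::tidy
tidy.chiralcat_result <- function(x, ...) {
  dplyr::arrange(x$importances, dplyr::desc(.data$importance))
}

#' One-row summary of a benchmark result
#'
#' @param x A `chiralcat_result` from [run_experiment()].
#' @param ... Unused.
#' @return One-row tibble with the experiment coordinates, the test metric
#'   and the split sizes.
#' @exportS3Method generics::glance
glance.chiralcat_result <- function(x, ...) {
  tibble::tibble(
    mode = x$spec$mode,
    target = x$spec$target,
    ligand_rep = x$spec$ligand_rep,
    substrate_rep = x$spec$substrate_rep,
    case_id = x$spec$case_id %||% NA_integer_,
    substrate = x$spec$substrate %||% NA_character_,
    split_seed = x$spec$split_seed,
    metric = x$metric_name,
    value = x$metric,
    n_train = x$n_train,
    n_test = x$n_test
  )
}

#' Tidy a PCA map
#'
#' @param x A `chiralcat_pca` from [pca_scores()].
#' @param ... Unused.
#' @return The loadings tibble (one row per feature).
#' @exportS3Method generics::tidy
tidy.chiralcat_pca <- function(x, ...) x$loadings

#' One-row summary of a PCA map
#'
#' @param x A `chiralcat_pca` from [pca_scores()].
#' @param ... Unused.
#' @return One-row tibble with the number of kept components and their
#'   cumulative explained variance (percent).
#' @exportS3Method generics::glance
glance.chiralcat_pca <- function(x, ...) {
  k <- ncol(x$scores)
  tibble::tibble(
    n_components = k,
    explained_variance = sum(x$explained_variance[seq_len(k)])
  )
}
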