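# PCA chemical-space maps of the catalyst descriptor table: a global score
# plot over all 34 descriptors plus per-category first-component cross
# sections (steric / geometric / electronic).

#' PCA scores of a standardized feature matrix
#'
#' Columns are standardized to zero mean and unit variance (idempotent for
#' already-standardized input); a constant column is an error instructing
#' its removal.  Component signs follow a deterministic rule -- the loading
#' of largest magnitude is made positive -- so reruns and row permutations
#' give identical maps.
#'
#' @param X Numeric matrix or data frame of features (rows = ligands).
#' @param n_components Number of components to keep (default 2).
#' @return A `chiralcat_pca`: list with `scores` (tibble), `loadings`
#'   (tibble, one row per feature) and `explained_variance` (percent, all
#'   components, non-increasing).
#' @export
pca_scores <- function(X, n_components = 2) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be numeric", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  const <- colnames(X)[sds == 0] %||% which(sds == 0)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(const, collapse = ", "),
         "; remove them before PCA", call. = FALSE)
  }
  if (n_components > min(dim(X))) {
    stop("n_components exceeds the matrix rank bound", call. = FALSE)
  }
  Z <- scale(X)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  # deterministic sign: largest-|loading| feature positive per component
  for (k in seq_len(ncol(pc$rotation))) {
    lead <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[lead, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ev <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  keep <- seq_len(n_components)
  scores <- tibble::as_tibble(pc$x[, keep, drop = FALSE])
  loadings <- dplyr::bind_cols(
    tibble::tibble(feature = colnames(X)),
    tibble::as_tibble(pc$rotation[, keep, drop = FALSE])
  )
  structure(
    list(scores = scores, loadings = loadings, explained_variance = ev),
    class = "chiralcat_pca"
  )
}

#' @export
print.chiralcat_pca <- function(x, ...) {
  cat(sprintf("<chiralcat_pca: %d components, EV%% = %s>\n",
              ncol(x$scores),
              paste(sprintf("%.1f", utils::head(x$explained_variance,
                                                ncol(x$scores))),
                    collapse = ", ")))
  invisible(x)
}

#' Per-category first-component cross sections
#'
#' Runs a separate PCA on each descriptor category (steric, geometric,
#' electronic) of a catalyst descriptor table and returns the three first
#' principal components side by side -- the cross-section coordinates used
#' to scan ligand space one property class at a time.
#'
#' @param descriptor_table Tibble with `ligand_id` and the
#'   [catalyst_schema()] columns.
#' @return Tibble with `ligand_id` and `steric_pc1`, `geometric_pc1`,
#'   `electronic_pc1`; per-category explained variance (percent of the
#'   category's PC1) in the `explained_variance` attribute.
#' @export
category_cross_sections <- function(descriptor_table) {
  schema <- catalyst_schema()
  out <- tibble::tibble(ligand_id = descriptor_table$ligand_id)
  ev <- c()
  for (cat in unique(schema$category)) {
    cols <- schema$name[schema$category == cat]
    cols <- intersect(cols, names(descriptor_table))
    if (length(cols) < 2) {
      stop("category '", cat, "' has fewer than 2 descriptor columns",
           call. = FALSE)
    }
    pc <- pca_scores(descriptor_table[, cols], n_components = 1)
    out[[paste0(cat, "_pc1")]] <- pc$scores$PC1
    ev[[cat]] <- pc$explained_variance[[1]]
  }
  attr(out, "explained_variance") <- ev
  out
}
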