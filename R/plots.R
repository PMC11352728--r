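# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Score plot of a PCA chemical-space map
#'
#' @param object A `chiralcat_pca` from [pca_scores()].
#' @param colour Optional vector (e.g. ligand family) mapped to colour.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.chiralcat_pca <- function(object, colour = NULL, ...) {
  df <- object$scores
  ev <- object$explained_variance
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (!is.null(colour)) {
    df$colour <- colour
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                          colour = .data$colour))
  }
  p +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", ev[[1]]),
      y = sprintf("PC2 (%.1f%%)", ev[[2]]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Feature-importance bar chart of a benchmark result
#'
#' @param result A `chiralcat_result` from [run_experiment()].
#' @param top_n Number of features shown (default 15).
#' @return A ggplot.
#' @export
plot_importances <- function(result, top_n = 15) {
  df <- utils::head(tidy(result), top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$feature, .data$importance)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "normalized Gini importance", y = NULL) +
    ggplot2::theme_minimal()
}

#' Conversion distribution per substrate
#'
#' Histograms of the (bimodal, high-skewed) conversion values with the
#' classification threshold marked.
#'
#' @param records HTE records.
#' @param threshold Class boundary to mark (default 0.8).
#' @return A ggplot.
#' @export
plot_conversion_distribution <- function(records, threshold = 0.8) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$conversion)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::facet_wrap(~substrate_id) +
    ggplot2::theme_minimal()
}

#' Inter-substrate rank-correlation heat map
#'
#' Spearman correlations of per-ligand outcomes between substrates, for
#' conversion or the ddG scale.
#'
#' @param records HTE records (one condition per substrate, e.g. the
#'   modeling subset).
#' @param value `"ddg"` or `"conversion"`.
#' @return A ggplot.
#' @export
plot_substrate_correlation <- function(records, value = c("ddg",
                                                          "conversion")) {
  value <- match.arg(value)
  m <- substrate_correlation(records, value)
  df <- tibble::as_tibble(as.table(m), .name_repair = "minimal")
  names(df) <- c("a", "b", "rho")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rho)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman") +
    ggplot2::theme_minimal()
}

#' Spearman correlation matrix of per-ligand outcomes across substrates
#'
#' @param records HTE records; wells are aggregated per ligand x substrate
#'   by the mean before ranking.
#' @param value `"ddg"` or `"conversion"`.
#' @return Symmetric correlation matrix (substrates x substrates).
#' @export
substrate_correlation <- function(records, value = c("ddg", "conversion")) {
  value <- match.arg(value)
  records <- tibble::as_tibble(records)
  records$.val <- if (value == "ddg") {
    ee_to_ddg(records$ee, records$temperature)
  } else {
    records$conversion
  }
  wide <- tidyr::pivot_wider(
    dplyr::summarise(
      dplyr::group_by(records, .data$ligand_id, .data$substrate_id),
      .val = mean(.data$.val), .groups = "drop"
    ),
    names_from = "substrate_id", values_from = ".val"
  )
  stats::cor(as.matrix(wide[, -1]), method = "spearman",
             use = "pairwise.complete.obs")
}
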