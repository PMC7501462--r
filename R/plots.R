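# ggplot2 autoplot() methods for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_point
#'   geom_step facet_wrap labs scale_fill_gradient2 theme_minimal
NULL

#' @export
ggplot2::autoplot

order_by_hclust <- function(mat) {
  if (nrow(mat) < 3) return(rownames(mat))
  rownames(mat)[stats::hclust(stats::dist(mat), method = "average")$order]
}

#' Heatmap of CO2-normalized pathway Z-scores
#'
#' Rows (pathways) are ordered by average-linkage hierarchical clustering on
#' Euclidean distance; the ordering is presentation only.
#'
#' @param object a `pathway_activity` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pathway_activity <- function(object, ...) {
  wide <- tidyr::pivot_wider(as_tibble(object)[, c("pathway", "condition",
                                                   "zscore")],
                             names_from = "condition",
                             values_from = "zscore", values_fill = 0)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$pathway
  lev <- order_by_hclust(m)
  df <- mutate(as_tibble(object),
               pathway = factor(.data$pathway, levels = lev))
  ggplot(df, aes(x = factor(.data$time_h), y = .data$pathway,
                 fill = .data$zscore)) +
    geom_tile() +
    facet_wrap(~strain, scales = "free_x") +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    labs(x = "time (h)", y = NULL, fill = "Z score") +
    theme_minimal()
}

#' Cultivation time-series overview
#'
#' @param object a `cultivation_ts`.
#' @param compounds columns to display (default all tracked plus cdw).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cultivation_ts <- function(object, compounds = NULL, ...) {
  if (is.null(compounds)) compounds <- c("cdw", ts_compounds(object))
  long <- tidyr::pivot_longer(as_tibble(object),
                              all_of(compounds),
                              names_to = "variable", values_to = "value")
  ggplot(long, aes(x = .data$time_h, y = .data$value)) +
    geom_line() +
    facet_wrap(~variable, scales = "free_y") +
    labs(x = "time (h)", y = NULL, title = object$strain[1]) +
    theme_minimal()
}

#' Cumulative flux-variability comparison
#'
#' @param object an `ecfva_comparison`.
#' @param ... unused.
#' @return a ggplot of the sorted range widths in the original and the
#'   enzyme-constrained model.
#' @export
autoplot.ecfva_comparison <- function(object, ...) {
  cum <- attr(object, "cumulative")
  long <- tidyr::pivot_longer(cum, c("gem_width", "ec_width"),
                              names_to = "model", values_to = "width")
  ggplot(long, aes(x = .data$width, y = .data$fraction,
                   colour = .data$model)) +
    geom_step() +
    labs(x = "flux variability range width (mmol/gDW/h)",
         y = "cumulative fraction of reactions", colour = NULL) +
    theme_minimal()
}

#' PCA score plot
#'
#' @param object a `pca_result`.
#' @param ... unused.
#' @return a ggplot of the first two components, coloured by time and
#'   shaped by strain.
#' @export
autoplot.pca_result <- function(object, ...) {
  stopifnot(ncol(object$loadings) >= 2)
  v <- object$variance$variance_pct
  ggplot(object$scores, aes(x = .data$PC1, y = .data$PC2,
                            colour = .data$time_h, shape = .data$strain)) +
    geom_point(size = 3) +
    labs(x = sprintf("PC1 (%.1f%%)", v[1]), y = sprintf("PC2 (%.1f%%)", v[2])) +
    theme_minimal()
}
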