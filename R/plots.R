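#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_tile
#'   geom_col geom_histogram geom_vline geom_segment labs theme_minimal
#'   scale_fill_gradient
#' @export
ggplot2::autoplot

#' Plot an iterative-PCA trajectory
#'
#' PC1 eigenvalue against the last month joined, with the detected
#' stability month (if stored) marked.
#'
#' @param object An `ecg_ipca`.
#' @param ... Unused.
#' @method autoplot ecg_ipca
#' @export
autoplot.ecg_ipca <- function(object, ...) {
  p <- ggplot(tidy(object), aes(x = .data$month, y = .data$pc1_eigenvalue)) +
    geom_line(colour = "grey50") +
    geom_point() +
    labs(x = "last month joined", y = "PC1 eigenvalue",
         title = paste0("Iterative PCA (reference month ",
                        attr(object, "reference_month"), ")")) +
    theme_minimal()
  sm <- attr(object, "stability_month")
  if (!is.null(sm) && !is.na(sm)) {
    p <- p + geom_vline(xintercept = sm, linetype = "dashed",
                        colour = "firebrick")
  }
  p
}

#' Plot PC1 projections with the selection cut
#'
#' Histogram of taxa projections along PC1 of the conserved covariance
#' matrix, with the fitted-GEV selection quantile marked.
#'
#' @param object An `ecg_ecogroup`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @method autoplot ecg_ecogroup
#' @export
autoplot.ecg_ecogroup <- function(object, bins = 30, ...) {
  df <- tidy(object)
  cut <- if (object$used_fallback) object$empirical_quantile
         else object$gev_quantile
  ggplot(df, aes(x = .data$projection_pc1)) +
    geom_histogram(bins = bins, fill = "grey70", colour = "white") +
    geom_vline(xintercept = cut, colour = "firebrick",
               linetype = "dashed") +
    labs(x = "projection along PC1", y = "taxa",
         title = sprintf("%d taxa beyond the %.0f%% threshold",
                         length(object$selected_taxa),
                         100 * object$threshold_fraction)) +
    theme_minimal()
}

#' Plot sample scores of an ordination
#'
#' @param object An `ecg_ordination`.
#' @param x_comp,y_comp Components plotted. Defaults PC1 and PC2.
#' @param colour Optional metadata column used for point colour
#'   (e.g. `"month"` or `"cohort"`).
#' @param ... Unused.
#' @method autoplot ecg_ordination
#' @export
autoplot.ecg_ordination <- function(object, x_comp = 1L, y_comp = 2L,
                                    colour = NULL, ...) {
  sc <- object$scores
  xs <- paste0("PC", x_comp); ys <- paste0("PC", y_comp)
  vf <- object$variance_fractions
  p <- ggplot(sc, aes(x = .data[[xs]], y = .data[[ys]]))
  p <- if (!is.null(colour)) {
    p + geom_point(aes(colour = .data[[colour]]))
  } else {
    p + geom_point()
  }
  p + labs(x = sprintf("%s (%.1f%%)", xs, 100 * vf[x_comp]),
           y = sprintf("%s (%.1f%%)", ys, 100 * vf[y_comp])) +
    theme_minimal()
}

#' Heat map of a conserved covariance matrix
#'
#' @param conserved Averaged binarized covariance matrix (see
#'   [average_tensor()]).
#' @param order Optional taxon ordering (e.g. ecogroup first).
#' @export
plot_conserved_matrix <- function(conserved, order = NULL) {
  if (!is.null(order)) {
    conserved <- conserved[order, order]
  }
  df <- tidy_pairs(conserved)
  lv <- rownames(conserved)
  df$taxon_a <- factor(df$taxon_a, levels = lv)
  df$taxon_b <- factor(df$taxon_b, levels = lv)
  ggplot(df, aes(x = .data$taxon_a, y = .data$taxon_b,
                 fill = .data$value)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "firebrick",
                        limits = c(0, 1), name = "<Cbin>") +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot a conserved-covariance network
#'
#' Force-directed layout of the thresholded network; node size tracks
#' degree, colour marks ecogroup membership.
#'
#' @param object An `ecg_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @method autoplot ecg_network
#' @export
autoplot.ecg_network <- function(object, seed = 1L, ...) {
  g <- object$graph
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- object$nodes
  nodes$x <- xy[, 1]; nodes$y <- xy[, 2]
  ed <- object$edges
  idx <- match(ed$taxon_a, nodes$taxon)
  jdx <- match(ed$taxon_b, nodes$taxon)
  ed$x <- nodes$x[idx]; ed$y <- nodes$y[idx]
  ed$xend <- nodes$x[jdx]; ed$yend <- nodes$y[jdx]
  ggplot() +
    geom_segment(data = ed,
                 aes(x = .data$x, y = .data$y,
                     xend = .data$xend, yend = .data$yend),
                 colour = "grey80", linewidth = 0.3) +
    geom_point(data = nodes,
               aes(x = .data$x, y = .data$y, size = .data$degree,
                   colour = .data$membership)) +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Monthly mean-abundance profile plot
#'
#' @param summary Output of [monthly_mean_abundance()].
#' @export
plot_monthly_abundance <- function(summary) {
  ggplot(summary, aes(x = .data$month, y = .data$mean,
                      fill = .data$taxon)) +
    geom_col(position = "stack") +
    labs(x = "postnatal month", y = "mean fractional abundance") +
    theme_minimal()
}
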