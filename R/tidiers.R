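#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a conserved-covariance eigendecomposition
#'
#' @param x An `ecg_eigen`.
#' @param ... Unused.
#' @return Tibble `taxon`, `projection_pc1`.
#' @method tidy ecg_eigen
#' @export
tidy.ecg_eigen <- function(x, ...) {
  tibble::tibble(taxon = x$taxon_ids, projection_pc1 = unname(x$projections_pc1))
}

#' @rdname tidy.ecg_eigen
#' @return For `glance`: one row per component with `component`,
#'   `eigenvalue`, `variance_fraction`.
#' @method glance ecg_eigen
#' @export
glance.ecg_eigen <- function(x, ...) {
  tibble::tibble(component = seq_along(x$values), eigenvalue = x$values,
                 variance_fraction = x$variance_fractions)
}

#' Tidy an ecogroup selection
#'
#' @param x An `ecg_ecogroup`.
#' @param ... Unused.
#' @return Tibble `taxon`, `projection_pc1`, `selected` (GEV-based),
#'   `selected_empirical`, sorted by projection descending.
#' @method tidy ecg_ecogroup
#' @export
tidy.ecg_ecogroup <- function(x, ...) {
  out <- tibble::tibble(
    taxon = names(x$projections),
    projection_pc1 = unname(x$projections),
    selected = names(x$projections) %in% x$selected_taxa,
    selected_empirical = names(x$projections) %in% x$selected_taxa_empirical
  )
  out[order(-out$projection_pc1), ]
}

#' @rdname tidy.ecg_ecogroup
#' @method glance ecg_ecogroup
#' @export
glance.ecg_ecogroup <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$selected_taxa),
    n_selected_empirical = length(x$selected_taxa_empirical),
    threshold_fraction = x$threshold_fraction,
    gev_location = unname(x$gev_params["location"]),
    gev_scale = unname(x$gev_params["scale"]),
    gev_shape = unname(x$gev_params["shape"]),
    gev_quantile = x$gev_quantile,
    used_fallback = x$used_fallback
  )
}

#' Tidy an ordination
#'
#' @param x An `ecg_ordination`.
#' @param matrix Which table: `"scores"` (default) or `"loadings"`.
#' @param ... Unused.
#' @method tidy ecg_ordination
#' @export
tidy.ecg_ordination <- function(x, matrix = c("scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") x$scores else x$loadings
}

#' @rdname tidy.ecg_ordination
#' @method glance ecg_ordination
#' @export
glance.ecg_ordination <- function(x, ...) {
  tibble::tibble(component = seq_along(x$variance_fractions),
                 variance_fraction = x$variance_fractions)
}

#' Tidy an iterative-PCA trajectory
#'
#' @param x An `ecg_ipca`.
#' @param ... Unused.
#' @method tidy ecg_ipca
#' @export
tidy.ecg_ipca <- function(x, ...) {
  tibble::tibble(month = x$month, pc1_eigenvalue = x$pc1_eigenvalue,
                 n_samples = x$n_samples)
}

#' @rdname tidy.ecg_ipca
#' @method glance ecg_ipca
#' @export
glance.ecg_ipca <- function(x, ...) {
  tibble::tibble(reference_month = attr(x, "reference_month"),
                 stability_month = attr(x, "stability_month"),
                 n_iterations = nrow(x))
}

#' Tidy a microbiota-age model
#'
#' @param x An `ecg_age_model`.
#' @param ... Unused.
#' @return The taxon importance ranking.
#' @method tidy ecg_age_model
#' @export
tidy.ecg_age_model <- function(x, ...) {
  out <- x$ranked_taxa
  out$rank <- seq_len(nrow(out))
  out$sparse <- if (is.null(x$sparse_taxa)) NA else out$taxon %in% x$sparse_taxa
  out
}

#' @rdname tidy.ecg_age_model
#' @method glance ecg_age_model
#' @export
glance.ecg_age_model <- function(x, ...) {
  tibble::tibble(
    n_taxa = length(x$taxa),
    n_sparse = if (is.null(x$sparse_taxa)) NA_integer_
               else length(x$sparse_taxa),
    n_trees = x$n_trees,
    train_mse = x$train_mse,
    full_cv_mse = if (is.null(x$full_cv_mse)) NA_real_ else x$full_cv_mse
  )
}

#' Tidy a covariance network
#'
#' @param x An `ecg_network`.
#' @param matrix `"edges"` (default) or `"nodes"`.
#' @param ... Unused.
#' @method tidy ecg_network
#' @export
tidy.ecg_network <- function(x, matrix = c("edges", "nodes"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "edges") x$edges else x$nodes
}

#' Long-format view of a labeled symmetric matrix
#'
#' Helper for inspecting conserved covariance matrices: one row per
#' unordered taxon pair (upper triangle).
#'
#' @param m A labeled symmetric matrix.
#' @return Tibble `taxon_a`, `taxon_b`, `value`.
#' @export
tidy_pairs <- function(m) {
  ut <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(taxon_a = rownames(m)[ut[, 1]],
                 taxon_b = colnames(m)[ut[, 2]],
                 value = m[ut])
}

#' @method print ecg_ecogroup
#' @export
print.ecg_ecogroup <- function(x, ...) {
  cat("Ecogroup selection (threshold fraction ", x$threshold_fraction,
      ")\n", sep = "")
  if (x$used_fallback) {
    cat("  GEV fit failed; empirical-quantile fallback used\n")
  } else {
    cat(sprintf("  GEV: location %.4g, scale %.4g, shape %.4g; cut %.4g\n",
                x$gev_params["location"], x$gev_params["scale"],
                x$gev_params["shape"], x$gev_quantile))
  }
  cat("  ", length(x$selected_taxa), " taxa selected (",
      length(x$selected_taxa_empirical), " by the empirical quantile)\n",
      sep = "")
  print(utils::head(x$selected_taxa, 20))
  invisible(x)
}

#' @method print ecg_discovery
#' @export
print.ecg_discovery <- function(x, ...) {
  cat("Ecogroup discovery over months ", min(x$months), "-", max(x$months),
      " (", length(x$months), " months, ",
      length(x$eigen$taxon_ids), " taxa)\n", sep = "")
  cat(sprintf("  PC1 variance fraction: %.3f\n",
              x$eigen$variance_fractions[1]))
  print(x$ecogroup)
  invisible(x)
}

#' @method print ecg_age_model
#' @export
print.ecg_age_model <- function(x, ...) {
  cat("Microbiota-age random forest (", x$n_trees, " trees, ",
      length(x$taxa), " taxa)\n", sep = "")
  if (!is.null(x$sparse_taxa)) {
    cat("  sparsified to ", length(x$sparse_taxa), " taxa\n", sep = "")
  }
  invisible(x)
}
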