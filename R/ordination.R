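#' Ordinate samples on a taxon subset
#'
#' Mean-centered, unscaled PCA of the samples restricted to the given
#' taxon columns (covariance PCA on raw fractional abundances). Component
#' signs are fixed so each component's largest-magnitude loading is
#' positive.
#'
#' @param table An abundance table.
#' @param taxon_subset Character vector of taxa to use; `NULL` uses all.
#' @param k Number of components retained. Default 3.
#' @param scale. Scale columns to unit variance before PCA (off by
#'   default; the workflow is covariance-based throughout).
#' @return An `ecg_ordination`: list with `scores` (tibble: sample
#'   metadata plus PC columns), `loadings` (tibble: taxon plus PC
#'   columns), `variance_fractions` (length k) and `taxon_subset`.
#' @export
ordinate_samples <- function(table, taxon_subset = NULL, k = 3L,
                             scale. = FALSE) {
  taxa <- taxa_of(table)
  if (is.null(taxon_subset)) taxon_subset <- taxa
  if (length(taxon_subset) == 0L) stop("taxon subset is empty")
  missing <- setdiff(taxon_subset, taxa)
  if (length(missing)) {
    stop("taxa not in table: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  m <- abundance_matrix(table)[, taxon_subset, drop = FALSE]
  if (nrow(m) < k + 1L) stop("need at least k + 1 samples")
  if (scale. && any(apply(m, 2, stats::sd) == 0)) {
    stop("cannot scale: constant taxon column")
  }
  p <- stats::prcomp(m, center = TRUE, scale. = scale.)
  k <- min(k, ncol(p$rotation))
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  sco <- p$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]; sco[, j] <- -sco[, j]
    }
  }
  vf <- p$sdev^2 / sum(p$sdev^2)
  meta <- table[, intersect(META_COLS, names(table))]
  structure(
    list(scores = dplyr::bind_cols(meta, tibble::as_tibble(sco)),
         loadings = tibble::as_tibble(rot, rownames = "taxon"),
         variance_fractions = vf[seq_len(k)],
         total_variance = sum(p$sdev^2),
         taxon_subset = taxon_subset),
    class = "ecg_ordination"
  )
}

#' Cohort centroids in an ordination space
#'
#' Arithmetic mean of sample scores per cohort.
#'
#' @param ord An `ecg_ordination`.
#' @param cohort Optional named character vector mapping `sample_id` to a
#'   cohort label; by default the table's `cohort` column (carried in the
#'   scores) is used.
#' @return A tibble with `cohort`, `n` and the mean score per component.
#' @export
compute_centroids <- function(ord, cohort = NULL) {
  stopifnot(inherits(ord, "ecg_ordination"))
  sc <- ord$scores
  if (is.null(cohort)) {
    if (!"cohort" %in% names(sc)) {
      stop("no cohort column in the scores and no cohort map supplied")
    }
  } else {
    unknown <- setdiff(sc$sample_id, names(cohort))
    if (length(unknown)) {
      stop("samples missing from the cohort map: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    sc$cohort <- unname(cohort[sc$sample_id])
  }
  if (any(is.na(sc$cohort))) stop("samples with missing cohort label")
  pcs <- grep("^PC", names(sc), value = TRUE)
  sc |>
    dplyr::group_by(.data$cohort) |>
    dplyr::summarise(n = dplyr::n(),
                     dplyr::across(dplyr::all_of(pcs), mean),
                     .groups = "drop")
}

#' Taxa ranked by loading magnitude on one component
#'
#' @param ord An `ecg_ordination`.
#' @param component Component number (1-based).
#' @param k Number of taxa returned; larger than available is truncated
#'   with a warning, `k = 0` returns an empty tibble.
#' @return Tibble `taxon`, `loading` sorted by |loading| descending, signs
#'   retained.
#' @export
top_loading_taxa <- function(ord, component = 1L, k = 10L) {
  stopifnot(inherits(ord, "ecg_ordination"))
  pc <- paste0("PC", component)
  if (!pc %in% names(ord$loadings)) {
    stop("component ", component, " not retained in the ordination")
  }
  ld <- tibble::tibble(taxon = ord$loadings$taxon,
                       loading = ord$loadings[[pc]])
  ld <- ld[order(-abs(ld$loading)), ]
  if (k > nrow(ld)) {
    warning("k exceeds the number of taxa; returning all ", nrow(ld))
    k <- nrow(ld)
  }
  ld[seq_len(k), ]
}

#' Per-month mean and SD of taxon fractional abundances
#'
#' @param table An abundance table.
#' @param taxon_subset Taxa summarized; `NULL` uses all.
#' @return A long tibble `month`, `taxon`, `mean`, `sd`, `n` (SD is `NA`
#'   for single-sample months).
#' @export
monthly_mean_abundance <- function(table, taxon_subset = NULL) {
  taxa <- taxa_of(table)
  if (is.null(taxon_subset)) taxon_subset <- taxa
  stopifnot(all(taxon_subset %in% taxa))
  if (nrow(table) == 0L) {
    return(tibble::tibble(month = integer(), taxon = character(),
                          mean = double(), sd = double(), n = integer()))
  }
  table |>
    dplyr::select(dplyr::all_of(c("month", taxon_subset))) |>
    tidyr::pivot_longer(-"month", names_to = "taxon",
                        values_to = "abundance") |>
    dplyr::group_by(.data$month, .data$taxon) |>
    dplyr::summarise(mean = mean(.data$abundance),
                     sd = stats::sd(.data$abundance),
                     n = dplyr::n(), .groups = "drop")
}
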