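#' Train a random-forest model of microbiota age
#'
#' Regresses chronologic age (postnatal month) on taxon fractional
#' abundances with a random forest and ranks taxa by permutation
#' importance: the mean increase in prediction mean squared error when a
#' taxon's values are randomly permuted, averaged over `importance_reps`
#' permutation repetitions. Taxa are placed in canonical sorted order
#' before fitting, so the ranking is invariant to the input column order
#' under a fixed seed.
#'
#' @param table An abundance table with a `month` for every sample.
#' @param n_trees Trees in the forest. Default 10000 (reduce for quick
#'   exploratory fits).
#' @param importance_reps Permutation repetitions per taxon. Default 100.
#' @param seed Integer seed controlling tree construction and the
#'   permutations.
#' @return An `ecg_age_model`: list with `forest`, `ranked_taxa` (tibble
#'   `taxon`, `importance`, descending), `taxa`, and (after
#'   [sparsify_age_model()]) `sparse_taxa`, `sparse_forest`,
#'   `cv_mse_curve`.
#' @export
train_age_model <- function(table, n_trees = 10000L, importance_reps = 100L,
                            seed = 0L) {
  if (nrow(table) < 10L) stop("need at least 10 samples to train")
  if (any(is.na(table$month))) stop("months required for all samples")
  taxa <- sort(taxa_of(table))
  x <- abundance_matrix(table)[, taxa, drop = FALSE]
  y <- as.numeric(table$month)
  set.seed(seed)
  forest <- randomForest::randomForest(x = x, y = y, ntree = n_trees)
  base_pred <- stats::predict(forest, x)
  base_mse <- mean((base_pred - y)^2)
  imp <- matrix(0, nrow = length(taxa), ncol = importance_reps,
                dimnames = list(taxa, NULL))
  n <- nrow(x)
  for (r in seq_len(importance_reps)) {
    for (j in seq_along(taxa)) {
      xp <- x
      xp[, j] <- xp[sample.int(n), j]
      imp[j, r] <- mean((stats::predict(forest, xp) - y)^2) - base_mse
    }
  }
  ranked <- tibble::tibble(taxon = taxa, importance = rowMeans(imp))
  ranked <- ranked[order(-ranked$importance), ]
  structure(
    list(forest = forest, ranked_taxa = ranked, taxa = taxa,
         train_mse = base_mse, n_trees = n_trees, seed = seed,
         sparse_taxa = NULL, sparse_forest = NULL, cv_mse_curve = NULL),
    class = "ecg_age_model"
  )
}

cv_mse_for_taxa <- function(x, y, taxa, n_splits, n_trees, seed) {
  set.seed(seed)
  n <- nrow(x)
  if (n >= 100L && n_splits <= n) {
    fold <- sample(rep(seq_len(n_splits), length.out = n))
    splits <- lapply(seq_len(n_splits), function(f) which(fold == f))
  } else {
    # repeated random 90/10 holdouts when exact k-fold is degenerate
    splits <- lapply(seq_len(n_splits), function(f) {
      sample.int(n, max(1L, round(0.1 * n)))
    })
  }
  errs <- vapply(splits, function(test) {
    train <- setdiff(seq_len(n), test)
    f <- randomForest::randomForest(x = x[train, taxa, drop = FALSE],
                                    y = y[train], ntree = n_trees)
    mean((stats::predict(f, x[test, taxa, drop = FALSE]) - y[test])^2)
  }, double(1))
  mean(errs)
}

#' Sparsify a microbiota-age model by cross-validation
#'
#' Evaluates nested models built from the top-n ranked taxa by
#' cross-validation (100-fold when there are at least 100 samples,
#' otherwise 100 repeated 90/10 holdouts; both counts adjustable via
#' `n_splits`) and keeps the smallest n whose CV mean squared error is
#' within `max_mse_inflation` (relative) of the all-taxa CV MSE.
#'
#' @param model An `ecg_age_model`.
#' @param table The abundance table used for cross-validation (normally
#'   the training table).
#' @param max_mse_inflation Allowed relative MSE inflation. Default 0.01
#'   (within 1% of the full model).
#' @param n_grid Candidate numbers of taxa; default a coarse grid up to
#'   the full taxon count.
#' @param n_splits Cross-validation folds / holdout repetitions.
#'   Default 100.
#' @param n_trees_cv Trees per CV fit (smaller than the final model for
#'   tractability). Default 500.
#' @param seed Integer seed for the CV splits.
#' @return The model with `sparse_taxa`, `sparse_forest` (refit on the
#'   selected taxa) and `cv_mse_curve` (tibble `n_taxa`, `cv_mse`) filled.
#' @export
sparsify_age_model <- function(model, table, max_mse_inflation = 0.01,
                               n_grid = NULL, n_splits = 100L,
                               n_trees_cv = 500L, seed = 0L) {
  stopifnot(inherits(model, "ecg_age_model"))
  taxa_ranked <- model$ranked_taxa$taxon
  p <- length(taxa_ranked)
  if (is.null(n_grid)) {
    n_grid <- unique(pmin(c(1L, 2L, 3L, 5L, 8L, 12L, 20L, 30L, 50L, 75L, p), p))
  }
  n_grid <- sort(unique(c(n_grid, p)))
  x <- abundance_matrix(table)[, model$taxa, drop = FALSE]
  y <- as.numeric(table$month)
  curve <- tibble::tibble(
    n_taxa = as.integer(n_grid),
    cv_mse = vapply(n_grid, function(nn) {
      cv_mse_for_taxa(x, y, taxa_ranked[seq_len(nn)], n_splits,
                      n_trees_cv, seed)
    }, double(1))
  )
  full_mse <- curve$cv_mse[curve$n_taxa == p]
  ok <- curve$n_taxa[curve$cv_mse <= full_mse * (1 + max_mse_inflation)]
  n_sel <- min(ok)
  model$cv_mse_curve <- curve
  model$full_cv_mse <- full_mse
  model$sparse_taxa <- taxa_ranked[seq_len(n_sel)]
  set.seed(seed)
  model$sparse_forest <- randomForest::randomForest(
    x = x[, model$sparse_taxa, drop = FALSE], y = y, ntree = model$n_trees)
  model
}

#' Predict microbiota age
#'
#' Applies a trained (optionally sparsified) model to an abundance table
#' and reports per-sample predicted age plus fit statistics against
#' chronologic age: the coefficient of determination R^2, mean absolute
#' error (MAE) and root mean square error (RMSE). Taxa absent from the
#' table are imputed as zero with a warning. R^2 is undefined for a
#' constant-age table and is reported as `NaN` with a warning.
#'
#' @param model An `ecg_age_model`.
#' @param table An abundance table.
#' @param use `"sparse"` (default, if sparsified) or `"full"`.
#' @return A list with `predictions` (tibble `sample_id`, `month`,
#'   `microbiota_age`) and `stats` (tibble `r_squared`, `mae`, `rmse`).
#' @export
predict_microbiota_age <- function(model, table,
                                   use = c("sparse", "full")) {
  stopifnot(inherits(model, "ecg_age_model"))
  use <- match.arg(use)
  if (use == "sparse" && is.null(model$sparse_forest)) use <- "full"
  forest <- if (use == "sparse") model$sparse_forest else model$forest
  need <- if (use == "sparse") model$sparse_taxa else model$taxa
  have <- taxa_of(table)
  missing <- setdiff(need, have)
  m <- matrix(0, nrow(table), length(need),
              dimnames = list(table$sample_id, need))
  present <- intersect(need, have)
  m[, present] <- abundance_matrix(table)[, present, drop = FALSE]
  if (length(missing)) {
    warning(length(missing), " model taxa absent from the table; imputed 0")
  }
  pred <- stats::predict(forest, m)
  y <- as.numeric(table$month)
  resid <- pred - y
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("chronologic age is constant; R^2 undefined (NaN)")
    r2 <- NaN
  } else {
    r2 <- 1 - sum(resid^2) / ss_tot
  }
  list(
    predictions = tibble::tibble(sample_id = table$sample_id,
                                 month = y, microbiota_age = unname(pred)),
    stats = tibble::tibble(r_squared = r2, mae = mean(abs(resid)),
                           rmse = sqrt(mean(resid^2)), model = use)
  )
}
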