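#' Monthly taxon-taxon covariance
#'
#' Sample covariance (denominator n - 1) of the taxon abundance columns
#' across one month's samples.
#'
#' @param m A samples-by-taxa numeric matrix for a single month.
#' @return A symmetric taxa-by-taxa covariance matrix.
#' @export
monthly_covariance <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (nrow(m) < 2L) {
    stop("insufficient samples for covariance (n = ", nrow(m), ")")
  }
  stats::cov(m)
}

#' Normalize a monthly covariance matrix
#'
#' Off-diagonal entries are divided by the month's maximum absolute
#' off-diagonal covariance, giving entries in \[-1, 1\]. The diagonal
#' (self-covariance) is set to zero: it is not taxon-taxon covariation and
#' would otherwise dominate the percentile pool used downstream.
#'
#' @param cov_m A symmetric covariance matrix.
#' @return The normalized matrix with zero diagonal.
#' @export
normalize_covariance <- function(cov_m) {
  if (!isSymmetric(unname(cov_m), tol = 1e-8)) {
    stop("covariance matrix must be symmetric")
  }
  out <- cov_m
  diag(out) <- 0
  mx <- max(abs(out))
  if (mx == 0) {
    warning("all off-diagonal covariances are zero; returning zero matrix")
    return(out)
  }
  out <- out / mx
  diag(out) <- 0
  out
}

upper_tri_values <- function(m) m[upper.tri(m)]

#' Binarize a normalized covariance matrix at its extreme deciles
#'
#' An entry becomes 1 when its value is at or above the
#' (100 - `upper_pct`)th percentile, or at or below the `lower_pct`th
#' percentile, of the month's off-diagonal upper-triangle values
#' (each taxon pair counted once); otherwise 0. Percentiles use the linear
#' interpolation definition ([stats::quantile()] type 7) and ties at either
#' cut are included as 1. Symmetry and the zero diagonal are preserved.
#' Both strong positive and strong negative covariation are flagged.
#'
#' @param norm_m A symmetric matrix with zero diagonal (see
#'   [normalize_covariance()]).
#' @param lower_pct,upper_pct Tail sizes, in percent. Defaults 10 and 10.
#' @return A binary matrix of the same shape.
#' @export
binarize_covariance <- function(norm_m, lower_pct = 10, upper_pct = 10) {
  t_dim <- nrow(norm_m)
  if (t_dim < 3L) stop("binarization needs at least 3 taxa")
  vals <- upper_tri_values(norm_m)
  qlo <- stats::quantile(vals, lower_pct / 100, names = FALSE, type = 7)
  qhi <- stats::quantile(vals, 1 - upper_pct / 100, names = FALSE, type = 7)
  flags <- (norm_m >= qhi) | (norm_m <= qlo)
  out <- matrix(0, t_dim, t_dim, dimnames = dimnames(norm_m))
  out[flags] <- 1
  diag(out) <- 0
  out
}

#' Build the stack of monthly binarized covariance matrices
#'
#' Applies [monthly_covariance()], [normalize_covariance()] and
#' [binarize_covariance()] to each monthly sample matrix. Months with fewer
#' than two samples cannot yield a covariance and are skipped with a
#' warning.
#'
#' @param matrices Named list of monthly samples-by-taxa matrices (see
#'   [split_by_month()]).
#' @param lower_pct,upper_pct Decile cuts passed to
#'   [binarize_covariance()].
#' @param keep_raw Keep the raw and normalized monthly matrices too.
#' @return An `ecg_tensor`: list with `months`, `taxon_ids`, `binarized`
#'   (list of binary matrices) and optionally `raw`, `normalized`.
#' @export
build_covariance_tensor <- function(matrices, lower_pct = 10, upper_pct = 10,
                                    keep_raw = FALSE) {
  usable <- vapply(matrices, nrow, integer(1)) >= 2L
  if (any(!usable)) {
    warning("skipping month(s) with a single sample: ",
            paste(names(matrices)[!usable], collapse = ", "))
  }
  matrices <- matrices[usable]
  if (length(matrices) < 2L) stop("need at least 2 months with >= 2 samples")
  raws <- lapply(matrices, monthly_covariance)
  norms <- lapply(raws, normalize_covariance)
  bins <- lapply(norms, binarize_covariance,
                 lower_pct = lower_pct, upper_pct = upper_pct)
  structure(
    list(months = as.integer(names(matrices)),
         taxon_ids = colnames(matrices[[1]]),
         binarized = bins,
         raw = if (keep_raw) raws,
         normalized = if (keep_raw) norms),
    class = "ecg_tensor"
  )
}

#' Temporally averaged binarized covariance
#'
#' Entrywise mean of the monthly binarized covariance matrices. An entry of
#' 1 means the pair's covariance sat in an extreme decile every month; 0
#' means it never did.
#'
#' @param tensor An `ecg_tensor` from [build_covariance_tensor()].
#' @return A symmetric taxa-by-taxa matrix with entries in \[0, 1\] and
#'   zero diagonal.
#' @export
average_tensor <- function(tensor) {
  stopifnot(inherits(tensor, "ecg_tensor"), length(tensor$binarized) >= 1L)
  out <- Reduce(`+`, tensor$binarized) / length(tensor$binarized)
  dimnames(out) <- list(tensor$taxon_ids, tensor$taxon_ids)
  out
}

#' Eigendecompose the conserved covariance matrix
#'
#' Eigendecomposition of the symmetric averaged binarized covariance
#' matrix, without centering: the matrix is itself the covariance-like
#' object of interest. Variance fractions are computed over the sum of the
#' positive eigenvalues; negative eigenvalues are reported but excluded
#' from the denominator. The first eigenvector's sign is fixed so that its
#' largest-magnitude entry is positive.
#'
#' @param conserved A symmetric matrix (see [average_tensor()]).
#' @return An `ecg_eigen`: list with `values` (descending),
#'   `variance_fractions`, `vectors` (columns aligned to values),
#'   `projections_pc1` (named), `taxon_ids`.
#' @export
eigendecompose <- function(conserved) {
  if (!isSymmetric(unname(conserved), tol = 1e-8)) {
    stop("conserved covariance matrix must be symmetric")
  }
  if (all(conserved == 0)) stop("no variance: conserved matrix is zero")
  e <- eigen(conserved, symmetric = TRUE)
  pos <- pmax(e$values, 0)
  vf <- pos / sum(pos)
  vecs <- e$vectors
  for (k in seq_len(ncol(vecs))) {
    if (vecs[which.max(abs(vecs[, k])), k] < 0) vecs[, k] <- -vecs[, k]
  }
  proj <- vecs[, 1]
  names(proj) <- rownames(conserved)
  structure(
    list(values = e$values, variance_fractions = vf, vectors = vecs,
         projections_pc1 = proj, taxon_ids = rownames(conserved)),
    class = "ecg_eigen"
  )
}

#' Select the ecogroup from PC1 projections
#'
#' Fits a generalized extreme value (GEV) distribution to the taxa's PC1
#' projections by maximum likelihood and selects the taxa whose projection
#' exceeds the fitted distribution's (1 - `threshold_fraction`) quantile.
#' The empirical top-`threshold_fraction` set (projections at or above the
#' empirical quantile) is recorded alongside, since either reading of a
#' "20% threshold" may be wanted. If the GEV fit fails, selection falls
#' back to the empirical quantile with a warning, and the fallback is
#' recorded in the result.
#'
#' @param spec An `ecg_eigen` from [eigendecompose()].
#' @param threshold_fraction Upper tail fraction. Default 0.20.
#' @return An `ecg_ecogroup`: list with `selected_taxa` (primary,
#'   GEV-based), `selected_taxa_empirical`, `gev_params`
#'   (location/scale/shape or NA on fallback), `gev_quantile`,
#'   `threshold_fraction`, `projections` and `used_fallback`.
#' @export
select_ecogroup <- function(spec, threshold_fraction = 0.20) {
  stopifnot(inherits(spec, "ecg_eigen"),
            threshold_fraction >= 0, threshold_fraction <= 1)
  proj <- spec$projections_pc1
  emp_q <- stats::quantile(proj, 1 - threshold_fraction, names = FALSE,
                           type = 7)
  empirical <- names(proj)[proj >= emp_q]
  fit <- tryCatch(fit_gev(proj), error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$loglik)) {
    warning("GEV fit failed; falling back to the empirical quantile")
    params <- c(location = NA_real_, scale = NA_real_, shape = NA_real_)
    q <- emp_q
    selected <- empirical
    fallback <- TRUE
  } else {
    params <- fit$params
    q <- if (threshold_fraction >= 1) {
      -Inf
    } else if (threshold_fraction <= 0) {
      Inf
    } else {
      qgev(1 - threshold_fraction, params["location"], params["scale"],
           params["shape"])
    }
    selected <- names(proj)[proj > q]
    fallback <- FALSE
  }
  structure(
    list(selected_taxa = selected, selected_taxa_empirical = empirical,
         gev_params = params, gev_quantile = unname(q),
         empirical_quantile = emp_q,
         threshold_fraction = threshold_fraction,
         projections = proj, used_fallback = fallback),
    class = "ecg_ecogroup"
  )
}

#' Sweep binarization and selection thresholds
#'
#' Recomputes the full pipeline (binarize, average, eigendecompose,
#' select) for every combination of decile cut and selection fraction and
#' reports the selected-set size and its Jaccard overlap with the default
#' (10/10 deciles, 0.20 selection) run.
#'
#' @param matrices Monthly sample matrices (see [split_by_month()]).
#' @param binarize_pcts Numeric vector of symmetric decile cuts (each used
#'   as both tails).
#' @param select_fractions Numeric vector of selection threshold fractions.
#' @return A tibble with columns `binarize_pct`, `select_fraction`,
#'   `n_selected`, `jaccard_default` and a list column `selected`.
#' @export
sweep_thresholds <- function(matrices, binarize_pcts = c(5, 10, 20),
                             select_fractions = c(0.1, 0.2, 0.3)) {
  if (length(binarize_pcts) == 0L || length(select_fractions) == 0L) {
    return(tibble::tibble(binarize_pct = double(), select_fraction = double(),
                          n_selected = integer(),
                          jaccard_default = double(), selected = list()))
  }
  run_once <- function(pct, frac) {
    tensor <- build_covariance_tensor(matrices, pct, pct)
    select_ecogroup(eigendecompose(average_tensor(tensor)), frac)$selected_taxa
  }
  default_set <- run_once(10, 0.20)
  grid <- expand.grid(binarize_pct = binarize_pcts,
                      select_fraction = select_fractions,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- tibble::as_tibble(grid)
  grid$selected <- purrr::map2(grid$binarize_pct, grid$select_fraction,
                               run_once)
  grid$n_selected <- lengths(grid$selected)
  grid$jaccard_default <- vapply(grid$selected, function(s) {
    length(intersect(s, default_set)) / length(union(s, default_set))
  }, double(1))
  grid[, c("binarize_pct", "select_fraction", "n_selected",
           "jaccard_default", "selected")]
}

#' Build the conserved-covariance network
#'
#' Two taxa are joined by an edge when their temporally averaged binarized
#' covariance is within the top `edge_fraction` of all pairwise values
#' (ties at the threshold included). Nodes carry their degree and an
#' ecogroup/peripheral label from the selection result.
#'
#' @param conserved Averaged binarized covariance matrix.
#' @param edge_fraction Fraction of pairs kept as edges. Default 0.20.
#' @param ecogroup An `ecg_ecogroup` sharing the matrix's taxa.
#' @return An `ecg_network`: list with `nodes` and `edges` tibbles and
#'   `graph`, an igraph object.
#' @export
build_network <- function(conserved, edge_fraction = 0.20, ecogroup = NULL) {
  taxa <- rownames(conserved)
  if (!is.null(ecogroup)) {
    stopifnot(inherits(ecogroup, "ecg_ecogroup"))
    if (!all(ecogroup$selected_taxa %in% taxa)) {
      stop("ecogroup taxa not present in the conserved matrix")
    }
  }
  ut <- which(upper.tri(conserved), arr.ind = TRUE)
  w <- conserved[ut]
  if (edge_fraction <= 0) {
    keep <- rep(FALSE, length(w))
  } else {
    thr <- stats::quantile(w, 1 - edge_fraction, names = FALSE, type = 7)
    keep <- w >= thr
  }
  edges <- tibble::tibble(
    taxon_a = taxa[ut[keep, 1]],
    taxon_b = taxa[ut[keep, 2]],
    weight = w[keep]
  )
  deg <- table(factor(c(edges$taxon_a, edges$taxon_b), levels = taxa))
  member <- if (is.null(ecogroup)) {
    rep(NA_character_, length(taxa))
  } else {
    ifelse(taxa %in% ecogroup$selected_taxa, "ecogroup", "peripheral")
  }
  nodes <- tibble::tibble(taxon = taxa, degree = as.integer(deg),
                          membership = member)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "ecg_network")
}

#' Run the full ecogroup discovery pipeline
#'
#' Convenience wrapper composing the whole workflow on an abundance table:
#' prevalence filter, within-month subject replicate averaging, monthly
#' split, covariance/normalization/binarization, temporal averaging,
#' eigendecomposition, GEV selection and network construction.
#'
#' @param table An abundance table.
#' @param months Month range used for covariance (e.g. the stable period
#'   `20:60`); `NULL` uses every month.
#' @param min_fraction,min_samples Prevalence filter (see [filter_taxa()]).
#' @param lower_pct,upper_pct Decile cuts (see [binarize_covariance()]).
#' @param threshold_fraction Selection fraction (see [select_ecogroup()]).
#' @param edge_fraction Network edge fraction (see [build_network()]).
#' @return An `ecg_discovery` list: `conserved`, `eigen`, `ecogroup`,
#'   `network`, `tensor`, plus the month range and parameters used.
#' @export
discover_ecogroup <- function(table, months = NULL,
                              min_fraction = 0.001, min_samples = 2L,
                              lower_pct = 10, upper_pct = 10,
                              threshold_fraction = 0.20,
                              edge_fraction = 0.20) {
  validate_abundance_table(table)
  table <- filter_taxa(table, min_fraction, min_samples)
  table <- collapse_subject_replicates(table)
  mats <- split_by_month(table, months)
  tensor <- build_covariance_tensor(mats, lower_pct, upper_pct)
  conserved <- average_tensor(tensor)
  spec <- eigendecompose(conserved)
  eco <- select_ecogroup(spec, threshold_fraction)
  net <- build_network(conserved, edge_fraction, eco)
  structure(
    list(conserved = conserved, eigen = spec, ecogroup = eco, network = net,
         tensor = tensor, months = tensor$months,
         params = list(min_fraction = min_fraction,
                       min_samples = min_samples, lower_pct = lower_pct,
                       upper_pct = upper_pct,
                       threshold_fraction = threshold_fraction,
                       edge_fraction = edge_fraction)),
    class = "ecg_discovery"
  )
}
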