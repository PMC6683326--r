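#' Iterative PCA against a reference month
#'
#' For each month m (ascending, excluding the reference month), a joined
#' sample matrix is formed, PCA is run on the sample vectors
#' (mean-centered, unscaled -- covariance PCA, consistent with the
#' covariance-based workflow), and the first principal component's
#' eigenvalue is recorded. The trajectory of PC1 eigenvalues flattens once
#' later months stop contributing structural variation;
#' [detect_asymptote()] locates that point.
#'
#' Two joinings are available. `"cumulative"` pools all months up to and
#' including m together with the reference month. `"pairwise"` pools only
#' month m with the reference month, so PC1 directly reflects the
#' dissimilarity between that month and the reference. Under a smooth
#' developmental drift the cumulative trajectory's increments shrink like
#' the weight of each newly added month in the pool (a dilution effect)
#' and can fall below any fixed tolerance before the community actually
#' stabilizes; the pairwise trajectory instead declines to its floor
#' exactly when monthly configurations stop moving relative to the
#' reference, at the cost of independent sampling jitter of a few percent
#' per iteration (use a `rel_tol` above that jitter, e.g. 0.05, when
#' detecting its asymptote).
#'
#' @param table An abundance table (filter taxa first if desired).
#' @param reference_month Month whose samples are pooled into every
#'   iteration (a mature reference configuration).
#' @param join `"cumulative"` (default) or `"pairwise"`; see Details.
#' @return An `ecg_ipca`: tibble with columns `month`, `pc1_eigenvalue`,
#'   `n_samples`, plus attributes `reference_month`, `join` and (after
#'   detection) `stability_month`.
#' @export
run_ipca <- function(table, reference_month,
                     join = c("cumulative", "pairwise")) {
  join <- match.arg(join)
  validate_abundance_table(table)
  ms <- sort(unique(table$month))
  if (!reference_month %in% ms) {
    stop("reference month ", reference_month, " not present in the table")
  }
  iter_months <- setdiff(ms, reference_month)
  if (length(iter_months) < 2L) stop("need at least 2 non-reference months")
  m_all <- abundance_matrix(table)
  month_of <- table$month
  ref_rows <- month_of == reference_month

  rows <- list(); lambdas <- double(); kept <- integer(); ns <- integer()
  for (mo in iter_months) {
    sel <- if (join == "cumulative") {
      (month_of <= mo & month_of != reference_month) | ref_rows
    } else {
      month_of == mo | ref_rows
    }
    n <- sum(sel)
    if (n < 2L) {
      warning("skipping iteration at month ", mo, ": fewer than 2 samples")
      next
    }
    x <- m_all[sel, , drop = FALSE]
    xc <- sweep(x, 2, colMeans(x))
    # PC1 eigenvalue of the sample covariance of the pooled samples
    lam1 <- svd(xc, nu = 0, nv = 0)$d[1]^2 / (n - 1)
    kept <- c(kept, mo); lambdas <- c(lambdas, lam1); ns <- c(ns, n)
  }
  out <- tibble::tibble(month = as.integer(kept), pc1_eigenvalue = lambdas,
                        n_samples = ns)
  attr(out, "reference_month") <- as.integer(reference_month)
  attr(out, "join") <- join
  attr(out, "stability_month") <- NA_integer_
  class(out) <- c("ecg_ipca", class(out))
  out
}

#' Locate the asymptote of an iterative-PCA trajectory
#'
#' Returns the earliest month at which the PC1 eigenvalue trajectory has
#' settled: the month m such that the relative changes arriving at months
#' m, m+1, ..., m+window-1 are all below `rel_tol`, where the change
#' arriving at month k is |lambda_k - lambda_(k-1)| / max(lambda_(k-1),
#' eps) and the change arriving at the first month is zero by convention
#' (a constant trajectory is stable from its first month).
#'
#' @param traj An `ecg_ipca` trajectory (needs at least `window + 1`
#'   points).
#' @param rel_tol Relative tolerance on consecutive eigenvalue changes.
#'   Default 0.02.
#' @param window Number of consecutive settled iterations required.
#'   Default 3.
#' @param eps Floor on the denominator. Default 1e-12.
#' @return The stability month (integer), or `NA_integer_` when no
#'   asymptote is found (a sentinel, not an error). The input trajectory's
#'   `stability_month` attribute is not modified; reassign if you want it
#'   stored: `attr(traj, "stability_month") <- detect_asymptote(traj)`.
#' @export
detect_asymptote <- function(traj, rel_tol = 0.02, window = 3L,
                             eps = 1e-12) {
  lam <- traj$pc1_eigenvalue
  n <- length(lam)
  if (n < window + 1L) stop("trajectory needs at least window + 1 points")
  rel <- c(0, abs(diff(lam)) / pmax(utils::head(lam, -1), eps))
  ok <- rel < rel_tol
  for (k in seq_len(n - window + 1L)) {
    if (all(ok[k:(k + window - 1L)])) return(traj$month[k])
  }
  NA_integer_
}
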