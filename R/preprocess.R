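#' Filter taxa by prevalence and minimum fractional abundance
#'
#' Retains exactly the taxa whose fractional abundance reaches
#' `min_fraction` in at least `min_samples` samples across the whole table
#' (all subjects and months pooled). Rows are not renormalized afterwards:
#' downstream analyses work with the retained taxa's raw fractions, so the
#' compositional denominator is left untouched. The filter is idempotent
#' and monotone (raising either cutoff can only remove taxa).
#'
#' @param table An abundance table.
#' @param min_fraction Minimum fractional abundance a sample must reach to
#'   count as a detection. Default 0.001 (0.1%).
#' @param min_samples Minimum number of qualifying samples. Default 2.
#' @return The abundance table restricted to retained taxa, column order
#'   preserved.
#' @export
filter_taxa <- function(table, min_fraction = 0.001, min_samples = 2L) {
  stopifnot(min_fraction >= 0, min_fraction <= 1, min_samples >= 1)
  taxa <- taxa_of(table)
  m <- abundance_matrix(table)
  n_detect <- colSums(m >= min_fraction)
  keep <- taxa[n_detect >= min_samples]
  if (length(keep) == 0L) {
    stop("filter removed all taxa (min_fraction = ", min_fraction,
         ", min_samples = ", min_samples, ")")
  }
  table[, c(intersect(META_COLS, names(table)), keep)]
}

#' Split an abundance table into monthly sample matrices
#'
#' One samples-by-taxa matrix is produced per postnatal month having at
#' least one sample; together the matrices partition the samples exactly.
#' All matrices share the same taxon columns in the same order.
#'
#' @param table An abundance table.
#' @param months Optional integer vector restricting which months are kept
#'   (e.g. `20:60`). `NULL` keeps every month present.
#' @return Named list of numeric matrices (names are the months, ascending).
#' @export
split_by_month <- function(table, months = NULL) {
  if (any(is.na(table$month))) stop("every sample needs a month")
  if (!is.null(months)) {
    if (length(months) == 0L) stop("empty month range")
    table <- table[table$month %in% months, , drop = FALSE]
    if (nrow(table) == 0L) stop("no samples in the requested month range")
  }
  ms <- sort(unique(table$month))
  out <- lapply(ms, function(mo) {
    abundance_matrix(table[table$month == mo, , drop = FALSE])
  })
  names(out) <- ms
  out
}

#' Average replicate samples of a subject within a month
#'
#' The covariance workflow assumes one observation per subject per month;
#' when a subject contributed several samples in the same calendar month
#' their fractional abundances are averaged first. Tables without
#' within-month replicates pass through unchanged (up to row order).
#'
#' @param table An abundance table.
#' @return An abundance table with one row per subject-month.
#' @export
collapse_subject_replicates <- function(table) {
  taxa <- taxa_of(table)
  grp <- c("subject", "month", intersect("cohort", names(table)))
  out <- table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      sample_id = dplyr::first(.data$sample_id),
      dplyr::across(dplyr::all_of(taxa), mean),
      .groups = "drop"
    )
  out[, c(intersect(META_COLS, names(table)), taxa)]
}
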