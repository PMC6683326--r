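#' @importFrom rlang .data
#' @import tibble
NULL

# Column names reserved for per-sample metadata; every other column of an
# abundance table is taken to be a taxon.
META_COLS <- c("sample_id", "subject", "month", "cohort")

#' Taxon columns of an abundance table
#'
#' An abundance table is an ordinary data frame (usually a tibble) with one
#' row per fecal sample, the metadata columns `sample_id`, `subject`,
#' `month` (integer postnatal month) and optionally `cohort`, and one
#' numeric column of fractional abundances per taxon. All functions in the
#' package operate on this shape.
#'
#' @param table An abundance table.
#' @return Character vector of taxon column names, in column order.
#' @export
taxa_of <- function(table) {
  setdiff(names(table), META_COLS)
}

#' Extract the samples-by-taxa abundance matrix
#'
#' @param table An abundance table.
#' @return Numeric matrix with `sample_id` row names and taxon column names.
#' @export
abundance_matrix <- function(table) {
  taxa <- taxa_of(table)
  m <- as.matrix(table[, taxa, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- table$sample_id
  m
}

#' Validate an abundance table
#'
#' Checks the structural invariants every downstream computation relies on:
#' unique sample and taxon identifiers, abundances in \[0, 1\], per-sample
#' row sums in (0, 1 + `tol`\], and a subject and integer month for every
#' sample.
#'
#' @param table An abundance table.
#' @param tol Tolerance on row sums exceeding 1 (fractions serialized as
#'   text can overshoot by rounding). Default `1e-6`.
#' @return The table, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_abundance_table <- function(table, tol = 1e-6) {
  if (!is.data.frame(table)) stop("abundance table must be a data frame")
  for (col in c("sample_id", "subject", "month")) {
    if (!col %in% names(table)) {
      stop("abundance table is missing required metadata column '", col, "'")
    }
  }
  if (anyDuplicated(table$sample_id)) {
    stop("duplicate sample_id values: ",
         paste(unique(table$sample_id[duplicated(table$sample_id)]),
               collapse = ", "))
  }
  taxa <- taxa_of(table)
  if (anyDuplicated(taxa)) stop("duplicate taxon identifiers")
  if (length(taxa) == 0L) stop("abundance table has no taxon columns")
  if (any(is.na(table$month)) || any(is.na(table$subject))) {
    stop("every sample needs a month and a subject; found missing metadata")
  }
  if (!is.numeric(table$month) || any(table$month %% 1 != 0) ||
      any(table$month < 1)) {
    stop("month must be a positive integer postnatal month")
  }
  m <- abundance_matrix(table)
  if (anyNA(m)) stop("abundances contain missing values")
  if (any(m < 0)) stop("negative abundances found")
  if (any(m > 1)) stop("abundances greater than 1 found; fractional ",
                       "abundances are required (see as_fractions =)")
  rs <- rowSums(m)
  bad <- which(rs <= 0 | rs > 1 + tol)
  if (length(bad)) {
    stop("per-sample abundance sums must lie in (0, 1]; offending samples: ",
         paste(utils::head(table$sample_id[bad], 5), collapse = ", "))
  }
  invisible(table)
}

#' Read an abundance table with sample metadata
#'
#' Reads a samples-by-taxa relative-abundance table plus a per-sample
#' metadata table and returns a validated abundance table. The TSV dialect
#' is: tab-separated, first column `sample_id`, remaining header fields the
#' taxon identifiers; metadata is a separate TSV keyed by `sample_id` with
#' columns `subject`, `month` and optionally `cohort`. BIOM-JSON tables
#' (taxa on the observation axis) are read through the biomformat package.
#'
#' @param path Path to the abundance table (TSV or BIOM-JSON).
#' @param metadata Path to the metadata TSV, or a data frame.
#' @param format `"tsv"` or `"biom-json"`.
#' @param as_fractions If `TRUE`, rows are counts and are divided by their
#'   row sum. Conversion is never performed silently.
#' @return A validated abundance table tibble.
#' @export
read_abundance_table <- function(path, metadata,
                                 format = c("tsv", "biom-json"),
                                 as_fractions = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    raw <- readr::read_tsv(path, show_col_types = FALSE)
    if (ncol(raw) < 2L) stop("malformed abundance table (", path,
                             "): need a sample_id column plus taxa")
    names(raw)[1] <- "sample_id"
    raw$sample_id <- as.character(raw$sample_id)
    numeric_ok <- vapply(raw[-1], is.numeric, logical(1))
    if (!all(numeric_ok)) {
      stop("malformed abundance table (", path, "): non-numeric field in ",
           "column(s) ", paste(names(raw)[-1][!numeric_ok], collapse = ", "))
    }
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM-JSON requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix") # taxa x samples
    raw <- tibble::as_tibble(t(m), rownames = "sample_id")
  }
  if (is.character(metadata)) {
    if (!file.exists(metadata)) stop("no such metadata file: ", metadata)
    metadata <- readr::read_tsv(metadata, show_col_types = FALSE)
  }
  if (!"sample_id" %in% names(metadata)) {
    stop("metadata must have a sample_id column")
  }
  metadata$sample_id <- as.character(metadata$sample_id)
  missing_meta <- setdiff(raw$sample_id, metadata$sample_id)
  if (length(missing_meta)) {
    stop("samples lacking metadata: ",
         paste(utils::head(missing_meta, 5), collapse = ", "))
  }
  keep <- intersect(c("sample_id", "subject", "month", "cohort"),
                    names(metadata))
  table <- dplyr::inner_join(metadata[, keep], raw, by = "sample_id")
  if (as_fractions) {
    taxa <- taxa_of(table)
    m <- as.matrix(table[, taxa, drop = FALSE])
    rs <- rowSums(m)
    if (any(rs <= 0)) stop("cannot convert counts: sample with zero total")
    table[, taxa] <- m / rs
  }
  validate_abundance_table(tibble::as_tibble(table))
  tibble::as_tibble(table)
}

#' Write / read a labeled numeric matrix as TSV
#'
#' Values are serialized with 17 significant digits so that
#' `read_matrix(write_matrix(M))` reproduces `M` to within 1e-12.
#'
#' @param m A numeric matrix with row and column names.
#' @param path Output path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns
#'   the matrix.
#' @export
write_matrix <- function(m, path) {
  if (!is.matrix(m) || length(m) == 0L) stop("need a non-empty matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("matrix must have row and column labels")
  }
  df <- tibble::as_tibble(m, rownames = "row_id")
  # readr keeps full double precision by default
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write the edges of a covariance network as TSV
#'
#' @param network An `ecg_network` (see [build_network()]).
#' @param path Output path for a `taxon_a`, `taxon_b`, `weight` edge list.
#' @export
write_network_edges <- function(network, path) {
  stopifnot(inherits(network, "ecg_network"))
  readr::write_tsv(network$edges, path)
  invisible(path)
}
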