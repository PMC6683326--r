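#' Aggregate gene-level transcript abundances into metabolic modules
#'
#' Sums normalized per-gene transcript abundances (e.g. TPM) over the
#' genes assigned to each metabolic module, per strain. Genes without a
#' module assignment are ignored (their count is reported in a message);
#' a gene mapped to several modules contributes to each of them.
#'
#' @param gene_tpm Data frame with a `gene` column and one numeric column
#'   per strain (genes by strains).
#' @param gene_to_module Data frame with columns `gene` and `module`
#'   (possibly several rows per gene).
#' @return A strains-by-modules tibble: `strain` column plus one numeric
#'   column per module.
#' @export
aggregate_by_module <- function(gene_tpm, gene_to_module) {
  stopifnot("gene" %in% names(gene_tpm),
            all(c("gene", "module") %in% names(gene_to_module)))
  if (nrow(gene_to_module) == 0L) stop("empty gene-to-module mapping")
  unmapped <- setdiff(gene_tpm$gene, gene_to_module$gene)
  if (length(unmapped)) {
    message(length(unmapped), " gene(s) without a module assignment ignored")
  }
  strains <- setdiff(names(gene_tpm), "gene")
  gene_tpm |>
    tidyr::pivot_longer(dplyr::all_of(strains), names_to = "strain",
                        values_to = "tpm") |>
    dplyr::inner_join(gene_to_module, by = "gene",
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$strain, .data$module) |>
    dplyr::summarise(tpm = sum(.data$tpm), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "module", values_from = "tpm",
                       values_fill = 0) |>
    dplyr::arrange(match(.data$strain, strains))
}

#' Module-expression enrichment relative to a reference strain
#'
#' Quantifies how the aggregate transcript level of each metabolic module
#' in each strain differs from a reference strain, as a pseudocounted
#' log2 ratio:
#' \deqn{E_{s,m} = \log_2\frac{x_{s,m} + p}{x_{\mathrm{ref},m} + p}.}
#' The reference row is identically zero by construction. The enrichment
#' definition is isolated here so alternatives (difference, z-score) can
#' be substituted; the definition and pseudocount used are recorded as
#' attributes of the result.
#'
#' @param mem Strains-by-modules tibble from [aggregate_by_module()].
#' @param reference Reference strain id, or `"auto"` to use the strain
#'   with the largest total module expression (a proxy for the most
#'   abundant strain).
#' @param pseudocount Added to numerator and denominator. Default 1
#'   (one TPM-aggregate unit).
#' @return A strains-by-modules tibble of enrichments with attributes
#'   `reference`, `pseudocount` and `definition`.
#' @export
compute_enrichment <- function(mem, reference = "auto", pseudocount = 1) {
  stopifnot("strain" %in% names(mem), pseudocount >= 0)
  mods <- setdiff(names(mem), "strain")
  x <- as.matrix(mem[, mods, drop = FALSE])
  rownames(x) <- mem$strain
  if (identical(reference, "auto")) {
    reference <- mem$strain[which.max(rowSums(x))]
  }
  if (!reference %in% mem$strain) stop("unknown reference strain: ", reference)
  ref <- x[reference, ]
  e <- log2(sweep(x + pseudocount, 2, ref + pseudocount, `/`))
  out <- dplyr::bind_cols(tibble::tibble(strain = mem$strain),
                          tibble::as_tibble(e))
  attr(out, "reference") <- reference
  attr(out, "pseudocount") <- pseudocount
  attr(out, "definition") <- "log2((x + p) / (x_ref + p))"
  out
}

#' Discriminatory modules by singular value decomposition
#'
#' SVD of the enrichment matrix relates the principal variation of strains
#' (left singular vectors) to the metabolic modules driving it (right
#' singular vectors). For each of the top `k` singular triplets, modules
#' are ranked by the magnitude of their right-singular-vector weight and
#' strains are scored by left singular vector times singular value.
#' Component signs are fixed so the largest-magnitude module weight is
#' positive.
#'
#' @param enrichment Strains-by-modules tibble from [compute_enrichment()].
#' @param k Number of singular triplets analyzed. Values beyond the matrix
#'   rank are truncated with a warning.
#' @return An `ecg_svd`: list with `module_rankings` (tibble `component`,
#'   `module`, `weight`, `rank`), `strain_scores` (tibble `strain` plus
#'   one column per component), `d` (singular values) and the trimmed
#'   `u`, `v` matrices.
#' @export
svd_discriminatory_modules <- function(enrichment, k = 2L) {
  stopifnot("strain" %in% names(enrichment))
  mods <- setdiff(names(enrichment), "strain")
  e <- as.matrix(enrichment[, mods, drop = FALSE])
  rownames(e) <- enrichment$strain
  if (all(e == 0)) stop("degenerate enrichment matrix (all zero)")
  s <- svd(e)
  rank_e <- sum(s$d > max(dim(e)) * .Machine$double.eps * s$d[1])
  if (k > rank_e) {
    warning("k = ", k, " exceeds the matrix rank (", rank_e,
            "); truncating")
    k <- rank_e
  }
  u <- s$u[, seq_len(k), drop = FALSE]
  v <- s$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (v[which.max(abs(v[, j])), j] < 0) {
      v[, j] <- -v[, j]; u[, j] <- -u[, j]
    }
  }
  rankings <- purrr::map_dfr(seq_len(k), function(j) {
    tb <- tibble::tibble(component = j, module = mods, weight = v[, j])
    tb <- tb[order(-abs(tb$weight)), ]
    tb$rank <- seq_len(nrow(tb))
    tb
  })
  scores <- sweep(u, 2, s$d[seq_len(k)], `*`)
  colnames(scores) <- paste0("SV", seq_len(k))
  structure(
    list(module_rankings = rankings,
         strain_scores = dplyr::bind_cols(
           tibble::tibble(strain = enrichment$strain),
           tibble::as_tibble(scores)),
         d = s$d, u = u, v = v),
    class = "ecg_svd"
  )
}

#' Cluster strains by their binary metabolic phenotypes
#'
#' Hierarchical clustering (average linkage) of strains under the Jaccard
#' distance on their binary phenotype rows, plus a PCA of the binary
#' matrix for visualization. Strains with identical phenotype rows have
#' distance zero and merge first; complementary rows have the maximal
#' distance 1.
#'
#' @param phenotypes Data frame with a `strain` column and 0/1 phenotype
#'   columns.
#' @return An `ecg_phenoclust`: list with `hclust`, `order` (strain ids in
#'   dendrogram order), `dist` and `scores` (PCA score tibble).
#' @export
cluster_by_phenotype <- function(phenotypes) {
  stopifnot("strain" %in% names(phenotypes))
  cols <- setdiff(names(phenotypes), "strain")
  b <- as.matrix(phenotypes[, cols, drop = FALSE])
  if (!all(b %in% c(0, 1))) stop("phenotype matrix must be binary")
  if (nrow(b) < 2L) stop("need at least 2 strains")
  rownames(b) <- phenotypes$strain
  d <- stats::dist(b, method = "binary") # Jaccard distance on binary rows
  hc <- stats::hclust(d, method = "average")
  p <- stats::prcomp(b, center = TRUE, scale. = FALSE)
  kk <- min(3L, ncol(p$x))
  structure(
    list(hclust = hc, order = rownames(b)[hc$order], dist = d,
         scores = dplyr::bind_cols(
           tibble::tibble(strain = phenotypes$strain),
           tibble::as_tibble(p$x[, seq_len(kk), drop = FALSE]))),
    class = "ecg_phenoclust"
  )
}
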