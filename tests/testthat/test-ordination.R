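test_that("collinear samples put all variance on PC1", {
  t_vals <- seq(0.1, 0.5, length.out = 6)
  tbl <- tibble::tibble(
    sample_id = paste0("s", 1:6), subject = paste0("p", 1:6),
    month = rep(1:2, 3),
    tax_A = t_vals, tax_B = 0.5 - t_vals / 2, tax_C = 0.5 - t_vals / 2
  )
  ord <- ordinate_samples(tbl, k = 3)
  expect_equal(ord$variance_fractions, c(1, 0, 0), tolerance = 1e-12)
  expect_error(ordinate_samples(tbl, character(0)), "empty")
})

test_that("sample duplication leaves scores and fractions unchanged", {
  sim <- small_planted(seed = 2, n_taxa = 15, months = 1:4,
                       module_size = 4, n_subjects = 6)
  tbl <- sim$table
  ord <- ordinate_samples(tbl, k = 2)
  dup <- dplyr::bind_rows(tbl, dplyr::mutate(
    tbl, sample_id = paste0(sample_id, "_d")))
  ord2 <- ordinate_samples(dup, k = 2)
  expect_equal(ord2$variance_fractions, ord$variance_fractions,
               tolerance = 1e-9)
  expect_equal(ord2$scores$PC1[seq_len(nrow(tbl))], ord$scores$PC1,
               tolerance = 1e-9)
})

test_that("ordination is invariant to taxon and sample order", {
  sim <- small_planted(seed = 3, n_taxa = 12, months = 1:3,
                       module_size = 3, n_subjects = 8)
  tbl <- sim$table
  ord <- ordinate_samples(tbl, k = 2)
  perm_taxa <- sample(taxa_of(tbl))
  perm_rows <- sample(nrow(tbl))
  tbl2 <- tbl[perm_rows, c("sample_id", "subject", "month", perm_taxa)]
  ord2 <- ordinate_samples(tbl2, k = 2)
  expect_equal(ord2$variance_fractions, ord$variance_fractions)
  m1 <- ord$scores[order(ord$scores$sample_id), c("PC1", "PC2")]
  m2 <- ord2$scores[order(ord2$scores$sample_id), c("PC1", "PC2")]
  expect_equal(as.matrix(m2), as.matrix(m1), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("component score variances add up to the total centered variance", {
  sim <- small_planted(seed = 4, n_taxa = 10, months = 1:3,
                       module_size = 3, n_subjects = 10)
  tbl <- sim$table
  m <- abundance_matrix(tbl)
  total <- sum(apply(m, 2, stats::var))
  ord <- ordinate_samples(tbl, k = ncol(m))
  sc <- as.matrix(ord$scores[, grep("^PC", names(ord$scores))])
  expect_equal(sum(apply(sc, 2, stats::var)), total, tolerance = 1e-10)
  expect_equal(ord$total_variance, total, tolerance = 1e-10)
})

test_that("the ecogroup subset captures the module-driven PC1 variance", {
  sim <- small_planted(seed = 5, months = 20:35)
  tbl <- sim$table
  planted <- planted_taxa(sim)
  full <- ordinate_samples(tbl, k = 3)
  sub <- ordinate_samples(tbl, planted, k = 3)
  expect_gte(sub$variance_fractions[1], full$variance_fractions[1])
})

test_that("cohort centroids average scores and mirror symmetric designs", {
  sc <- tibble::tibble(
    sample_id = paste0("s", 1:4), subject = paste0("p", 1:4),
    month = 1L, cohort = c("x", "x", "y", "y"),
    PC1 = c(1, 3, -1, -3), PC2 = c(0, 2, 0, -2)
  )
  ord <- structure(list(scores = sc, variance_fractions = c(0.6, 0.4)),
                   class = "ecg_ordination")
  cen <- compute_centroids(ord)
  expect_equal(cen$PC1[cen$cohort == "x"], 2)
  expect_equal(cen$PC1[cen$cohort == "y"], -2)
  expect_equal(cen$PC2[cen$cohort == "x"], -cen$PC2[cen$cohort == "y"])
  # single-sample cohort equals its score; unknown sample errors
  cen1 <- compute_centroids(ord, cohort = c(s1 = "solo", s2 = "rest",
                                            s3 = "rest", s4 = "rest"))
  expect_equal(cen1$PC1[cen1$cohort == "solo"], 1)
  expect_error(compute_centroids(ord, cohort = c(s1 = "a")), "missing")
})

test_that("cohort states separate along PC1 beyond the within-cohort spread", {
  sim <- generate_community(synthetic_preset("two_cohort_treatment",
                                             seed = 2))
  tbl <- sim$table
  ord <- ordinate_samples(tbl, k = 2)
  cen <- compute_centroids(ord)
  spread <- ord$scores |>
    dplyr::group_by(.data$cohort) |>
    dplyr::summarise(s = stats::sd(.data$PC1))
  sep <- abs(diff(cen$PC1))
  expect_gt(sep, max(spread$s))
})

test_that("top loadings rank the planted module first", {
  sim <- small_planted(seed = 6, months = 20:31)
  planted <- planted_taxa(sim)
  ord <- ordinate_samples(sim$table, k = 2)
  top <- top_loading_taxa(ord, 1, length(planted))
  expect_gte(length(intersect(top$taxon, planted)), length(planted) - 2)
  expect_equal(nrow(top_loading_taxa(ord, 1, 0)), 0L)
  expect_warning(big <- top_loading_taxa(ord, 1, 1000), "exceeds")
  expect_equal(nrow(big), length(taxa_of(sim$table)))
  expect_error(top_loading_taxa(ord, 5, 3), "not retained")
})

test_that("monthly means and SDs match hand computation", {
  tbl <- tibble::tibble(
    sample_id = paste0("s", 1:4), subject = paste0("p", 1:4),
    month = c(1L, 1L, 2L, 2L),
    tax_A = c(0.2, 0.4, 0.6, 0.6), tax_B = c(0.8, 0.6, 0.4, 0.4)
  )
  mm <- monthly_mean_abundance(tbl)
  a1 <- mm[mm$month == 1 & mm$taxon == "tax_A", ]
  expect_equal(a1$mean, 0.3)
  expect_equal(a1$sd, stats::sd(c(0.2, 0.4)))
  a2 <- mm[mm$month == 2 & mm$taxon == "tax_A", ]
  expect_equal(a2$sd, 0) # constant abundances
  expect_equal(nrow(monthly_mean_abundance(tbl[0, ])), 0L)
})
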