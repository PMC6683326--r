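test_that("module aggregation sums member genes per strain", {
  tpm <- tibble::tibble(gene = c("g1", "g2", "g3"),
                        strainA = c(10, 5, 2), strainB = c(0, 1, 4))
  map <- tibble::tibble(gene = c("g1", "g2"), module = "mod1")
  expect_message(mem <- aggregate_by_module(tpm, map), "without a module")
  expect_equal(mem$mod1[mem$strain == "strainA"], 15)
  expect_equal(mem$mod1[mem$strain == "strainB"], 1)
  # a gene mapped to two modules contributes to both
  map2 <- tibble::tibble(gene = c("g1", "g1", "g2", "g3"),
                         module = c("mod1", "mod2", "mod1", "mod2"))
  mem2 <- aggregate_by_module(tpm, map2)
  expect_equal(mem2$mod2[mem2$strain == "strainA"], 12)
  # gene order is irrelevant
  mem3 <- aggregate_by_module(tpm[c(3, 1, 2), ], map2)
  expect_equal(mem3, mem2)
  expect_error(aggregate_by_module(tpm, map[0, ]), "empty")
})

test_that("enrichment is a pseudocounted log2 ratio with a zero reference row", {
  mem <- tibble::tibble(strain = c("ref", "s1", "s2"),
                        m1 = c(100, 200, 100), m2 = c(0, 0, 50))
  e <- compute_enrichment(mem, reference = "ref", pseudocount = 1)
  expect_equal(unlist(e[e$strain == "ref", c("m1", "m2")]),
               c(m1 = 0, m2 = 0))
  # doubling at large values is close to +1
  expect_equal(e$m1[e$strain == "s1"], log2(201 / 101), tolerance = 1e-12)
  expect_lt(abs(e$m1[e$strain == "s1"] - 1), 0.02)
  # zero in both strains stays zero through the pseudocount
  expect_equal(e$m2[e$strain == "s1"], 0)
  # auto reference picks the strain with the largest total expression
  e_auto <- compute_enrichment(mem, reference = "auto")
  expect_equal(attr(e_auto, "reference"), "s1")
  expect_error(compute_enrichment(mem, reference = "zz"), "unknown")
})

test_that("swapping the reference negates the matrix as pseudocount vanishes", {
  mem <- tibble::tibble(strain = c("a", "b"),
                        m1 = c(8, 2), m2 = c(16, 64))
  ea <- compute_enrichment(mem, "a", pseudocount = 1e-9)
  eb <- compute_enrichment(mem, "b", pseudocount = 1e-9)
  expect_equal(as.matrix(ea[, -1]), -as.matrix(eb[c(2, 1), -1]),
               ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("SVD isolates the module constructed to differ", {
  mem <- tibble::tibble(
    strain = c("ref", paste0("s", 1:3)),
    modA = c(10, 80, 80, 80),  # the one real difference
    modB = rep(20, 4), modC = rep(5, 4))
  e <- compute_enrichment(mem, "ref")
  sv <- svd_discriminatory_modules(e, k = 1)
  top <- sv$module_rankings[sv$module_rankings$rank == 1, ]
  expect_equal(top$module, "modA")
  # rank-1 input: second singular value vanishes
  expect_lt(sv$d[2] / sv$d[1], 1e-10)
  expect_error(
    svd_discriminatory_modules(
      tibble::tibble(strain = c("a", "b"), m = c(0, 0))), "degenerate")
})

test_that("kept triplets reconstruct the enrichment matrix at full rank", {
  set.seed(2)
  mem <- dplyr::bind_cols(
    tibble::tibble(strain = paste0("s", 1:5)),
    tibble::as_tibble(matrix(rexp(5 * 7, 0.05), 5, 7,
                             dimnames = list(NULL, paste0("m", 1:7)))))
  e <- compute_enrichment(mem, "s1")
  em <- as.matrix(e[, -1])
  sv <- suppressWarnings(svd_discriminatory_modules(e, k = 7))
  rec <- sv$u %*% diag(sv$d[seq_len(ncol(sv$u))]) %*% t(sv$v)
  expect_lt(max(abs(rec - em)), 1e-9)
  expect_warning(svd_discriminatory_modules(e, k = 7), "rank")
})

test_that("phenotype clustering follows brute-force Jaccard distances", {
  b <- tibble::tibble(
    strain = c("w", "x", "y", "z"),
    p1 = c(1, 1, 0, 0), p2 = c(1, 1, 1, 0), p3 = c(0, 0, 1, 1))
  res <- cluster_by_phenotype(b)
  # brute-force pairwise Jaccard distance: 1 - |intersect| / |union|
  jac <- function(u, v) {
    on <- (u + v) > 0
    1 - sum(u == 1 & v == 1) / sum(on)
  }
  m <- as.matrix(b[, -1])
  expected <- c(jac(m[1,], m[2,]), jac(m[1,], m[3,]), jac(m[1,], m[4,]),
                jac(m[2,], m[3,]), jac(m[2,], m[4,]), jac(m[3,], m[4,]))
  expect_equal(as.vector(res$dist), expected)
  # identical rows merge first
  b2 <- tibble::tibble(strain = c("a", "b", "c"),
                       p1 = c(1, 1, 0), p2 = c(0, 0, 1))
  r2 <- cluster_by_phenotype(b2)
  expect_equal(as.matrix(r2$dist)["a", "b"], 0)
  first_merge <- r2$hclust$merge[1, ]
  expect_setequal(abs(first_merge), c(1, 2))
  # complementary rows are maximally distant
  expect_equal(as.matrix(r2$dist)["a", "c"], 1)
  expect_error(cluster_by_phenotype(b[1, ]), "2 strains")
  expect_error(cluster_by_phenotype(
    tibble::tibble(strain = "a", p1 = 0.5)), "binary")
})
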