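test_that("monthly covariance matches hand computation", {
  m <- cbind(a = c(0.1, 0.2, 0.3), b = c(0.3, 0.2, 0.1))
  cv <- monthly_covariance(m)
  expect_equal(cv["a", "b"], -0.01)
  expect_equal(cv["a", "a"], 0.01)
  expect_true(isSymmetric(cv))
  expect_error(monthly_covariance(m[1, , drop = FALSE]), "insufficient")
  # constant taxon gives a zero row/column
  m2 <- cbind(m, c = c(0.5, 0.5, 0.5))
  expect_equal(unname(monthly_covariance(m2)[, "c"]), rep(0, 3))
})

test_that("normalization scales by the maximum absolute off-diagonal", {
  m <- sym_from_upper(c(0.02, -0.04, 0.01), 3)
  diag(m) <- 5 # diagonal must not enter the normalization pool
  out <- normalize_covariance(m)
  expect_equal(out["t1", "t2"], 0.5)
  expect_equal(out["t1", "t3"], -1.0)
  expect_equal(unname(diag(out)), rep(0, 3))
  # idempotent once the maximum is 1
  expect_equal(normalize_covariance(out), out)
  # property: any normalized matrix has max |entry| exactly 1
  set.seed(9)
  r <- sym_from_upper(rnorm(10), 5)
  expect_equal(max(abs(normalize_covariance(r))), 1)
  expect_warning(normalize_covariance(matrix(0, 3, 3)), "zero")
})

test_that("binarization flags the extreme deciles, ties included", {
  vals <- c(-0.9, -0.5, -0.1, -0.05, 0, 0.05, 0.1, 0.5, 0.9, 0.3)
  m <- sym_from_upper(vals, 5)
  b <- binarize_covariance(m, 20, 20)
  expect_equal(b, oracle_binarize(m, 20, 20))
  expect_true(isSymmetric(b))
  expect_equal(unname(diag(b)), rep(0, 5))
  # degenerate all-equal matrix: every value sits at both extremes
  eq <- sym_from_upper(rep(0.3, 10), 5)
  expect_true(all(binarize_covariance(eq)[upper.tri(eq)] == 1))
  expect_error(binarize_covariance(matrix(0, 2, 2)), "at least 3")
})

test_that("binarization equals the sorting oracle on random matrices", {
  set.seed(17)
  for (i in 1:50) {
    t_dim <- sample(5:20, 1)
    m <- sym_from_upper(rnorm(t_dim * (t_dim - 1) / 2), t_dim)
    for (pct in c(5, 10, 20, 25)) {
      expect_identical(binarize_covariance(m, pct, pct),
                       oracle_binarize(m, pct, pct))
    }
  }
})

test_that("the tensor pipeline skips single-sample months and averages slices", {
  sim <- small_planted(seed = 2, months = 20:25)
  tbl <- sim$table
  # duplicate months give identical slices
  mats <- split_by_month(tbl)
  tensor <- build_covariance_tensor(mats[c(1, 1, 2)])
  expect_identical(tensor$binarized[[1]], tensor$binarized[[2]])
  # slice count equals usable months
  expect_length(build_covariance_tensor(mats)$binarized, 6)
  # single-sample month skipped with warning
  mats_bad <- c(mats, list(`99` = mats[[1]][1, , drop = FALSE]))
  expect_warning(t2 <- build_covariance_tensor(mats_bad), "single sample")
  expect_length(t2$binarized, 6)

  cons <- average_tensor(build_covariance_tensor(mats))
  expect_true(all(cons >= 0 & cons <= 1))
  expect_true(isSymmetric(cons))
  expect_equal(unname(diag(cons)), rep(0, ncol(cons)))
  # entry = mean of the per-month flags
  flags <- vapply(build_covariance_tensor(mats)$binarized,
                  function(b) b[1, 2], double(1))
  expect_equal(cons[1, 2], mean(flags))
})

test_that("eigendecomposition handles rank-1, block and degenerate inputs", {
  v <- c(0.8, 0.5, 0.2, 0.1)
  r1 <- v %*% t(v)
  dimnames(r1) <- list(paste0("t", 1:4), paste0("t", 1:4))
  spec <- eigendecompose(r1)
  expect_equal(spec$variance_fractions[1], 1)
  expect_true(all(diff(spec$values) <= 1e-12))

  # two disjoint perfect modules, sizes 3 and 2: blocks of ones minus the
  # diagonal have leading eigenvalues m - 1 = 2 and 1
  b <- matrix(0, 6, 6, dimnames = list(paste0("t", 1:6), paste0("t", 1:6)))
  b[1:3, 1:3] <- 1; b[4:5, 4:5] <- 1; diag(b) <- 0
  spec2 <- eigendecompose(b)
  expect_equal(spec2$values[1:2], c(2, 1))
  pos <- pmax(spec2$values, 0)
  expect_equal(spec2$variance_fractions[1:2], c(2, 1) / sum(pos))
  expect_equal(sum(spec2$variance_fractions), 1, tolerance = 1e-9)

  expect_error(eigendecompose(matrix(0, 3, 3)), "no variance")
  ns <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_error(eigendecompose(ns), "symmetric")
  # sign convention: largest-magnitude PC1 entry is positive
  expect_gt(spec$projections_pc1[which.max(abs(spec$projections_pc1))], 0)
})

test_that("ecogroup selection thresholds behave at the limits and nest", {
  sim <- small_planted(seed = 1)
  cons <- average_tensor(build_covariance_tensor(
    split_by_month(sim$table)))
  spec <- eigendecompose(cons)
  eco <- select_ecogroup(spec, 0.20)
  expect_true(all(eco$selected_taxa %in% spec$taxon_ids))
  expect_false(eco$used_fallback)
  # threshold 1.0 selects everything (empirical set)
  all_sel <- select_ecogroup(spec, 1.0)
  expect_setequal(all_sel$selected_taxa_empirical, spec$taxon_ids)
  # monotone nesting over growing fractions
  sets <- lapply(c(0.05, 0.10, 0.20, 0.30),
                 function(f) select_ecogroup(spec, f)$selected_taxa)
  for (i in 1:3) expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

test_that("an indicator-like projection vector selects exactly the planted taxa", {
  proj <- c(rep(1, 3), abs(rnorm(12, 0, 1e-3)))
  names(proj) <- paste0("t", 1:15)
  spec <- structure(list(projections_pc1 = proj,
                         taxon_ids = names(proj)),
                    class = "ecg_eigen")
  eco <- suppressWarnings(select_ecogroup(spec, 0.20))
  expect_setequal(eco$selected_taxa_empirical, c("t1", "t2", "t3"))
})

test_that("threshold sweep reports set sizes and overlap with the default", {
  mats <- split_by_month(small_planted(seed = 4, months = 20:31)$table)
  sw <- sweep_thresholds(mats, binarize_pcts = c(5, 10),
                         select_fractions = c(0.1, 0.2))
  expect_equal(nrow(sw), 4L)
  def <- sw[sw$binarize_pct == 10 & sw$select_fraction == 0.2, ]
  expect_equal(def$jaccard_default, 1.0)
  # stricter binarization still recovers most of the planted module
  planted <- planted_taxa(small_planted(seed = 4, months = 20:31))
  strict <- sw$selected[[which(sw$binarize_pct == 5 &
                                 sw$select_fraction == 0.2)]]
  expect_gte(length(intersect(strict, planted)) / length(planted), 0.8)
  # empty sweep
  expect_equal(nrow(sweep_thresholds(mats, numeric(0), numeric(0))), 0L)
})

test_that("network construction thresholds edges and labels membership", {
  cons <- sym_from_upper(rep(0.1, 45), 10)
  for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
    cons[p[1], p[2]] <- cons[p[2], p[1]] <- 1
  }
  eco <- structure(list(selected_taxa = c("t1", "t2", "t3")),
                   class = "ecg_ecogroup")
  net <- build_network(cons, edge_fraction = 0.05, ecogroup = eco)
  expect_equal(nrow(net$edges), 3L)
  expect_setequal(
    net$nodes$taxon[net$nodes$degree == 2], c("t1", "t2", "t3"))
  expect_equal(net$nodes$membership[net$nodes$taxon == "t1"], "ecogroup")
  expect_equal(net$nodes$membership[net$nodes$taxon == "t9"], "peripheral")
  # degree equals incident edge count in the igraph view too
  expect_equal(unname(igraph::degree(net$graph)[net$nodes$taxon]),
               net$nodes$degree)
  # zero edge fraction
  expect_equal(nrow(build_network(cons, 0)$edges), 0L)
  # all-equal matrix: everything ties at the threshold and is kept
  eq <- sym_from_upper(rep(0.4, 45), 10)
  expect_equal(nrow(build_network(eq, 0.2)$edges), 45L)
})

test_that("the discovery pipeline is equivariant to taxon permutation", {
  sim <- small_planted(seed = 6, n_taxa = 30, months = 20:29,
                       module_size = 5)
  tbl <- sim$table
  d1 <- discover_ecogroup(tbl, months = 20:29)
  perm <- sample(taxa_of(tbl))
  tbl2 <- tbl[, c("sample_id", "subject", "month", perm)]
  d2 <- discover_ecogroup(tbl2, months = 20:29)
  expect_setequal(d1$ecogroup$selected_taxa, d2$ecogroup$selected_taxa)
  expect_equal(d1$conserved[perm, perm], d2$conserved)
  expect_equal(d1$eigen$values, d2$eigen$values)
})

test_that("tidiers expose projections, spectra and networks as tibbles", {
  sim <- small_planted(seed = 1)
  disc <- discover_ecogroup(sim$table, months = 20:40)
  td <- tidy(disc$ecogroup)
  expect_true(all(c("taxon", "projection_pc1", "selected") %in% names(td)))
  expect_equal(nrow(td), length(disc$eigen$taxon_ids))
  gl <- glance(disc$eigen)
  expect_equal(sum(gl$variance_fraction), 1, tolerance = 1e-9)
  expect_equal(nrow(tidy(disc$network, "nodes")), 60)
})
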