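# Small fixtures built in code.

# A minimal valid abundance table: 3 samples, 2 taxa, fractions sum to 1.
tiny_table <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    subject = c("a", "b", "c"),
    month = c(1L, 1L, 2L),
    tax_A = c(0.6, 0.5, 1.0),
    tax_B = c(0.4, 0.5, 0.0)
  )
}

# Deterministic planted-module table at reduced scale for pipeline tests.
small_planted <- function(seed = 1, n_taxa = 60, n_subjects = 24,
                          months = 20:40, module_size = 8) {
  cfg <- synthetic_config(
    n_subjects = n_subjects, months = months, n_taxa = n_taxa,
    modules = list(list(members = seq_len(module_size),
                        signs = c(rep(1, module_size - 2), -1, -1),
                        coupling = 0.9)),
    noise_scale = 0.6, baseline_sd = 0.1, seed = seed
  )
  generate_community(cfg)
}

planted_taxa <- function(sim) {
  mm <- sim$truth$module_membership
  mm$taxon[!is.na(mm$module)]
}

# Symmetric matrix with zero diagonal from an upper-triangle value vector.
sym_from_upper <- function(vals, t_dim) {
  stopifnot(length(vals) == t_dim * (t_dim - 1) / 2)
  m <- matrix(0, t_dim, t_dim)
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  dimnames(m) <- list(paste0("t", seq_len(t_dim)), paste0("t", seq_len(t_dim)))
  m
}

# Independent percentile oracle: explicit sorting plus the linear
# interpolation formula, written without stats::quantile.
oracle_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

oracle_binarize <- function(m, lower_pct, upper_pct) {
  vals <- m[upper.tri(m)]
  qlo <- oracle_percentile(vals, lower_pct / 100)
  qhi <- oracle_percentile(vals, 1 - upper_pct / 100)
  out <- ifelse(m >= qhi | m <= qlo, 1, 0)
  diag(out) <- 0
  dimnames(out) <- dimnames(m)
  out
}
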