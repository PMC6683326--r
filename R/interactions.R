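#' Count pairwise and higher-order interaction terms
#'
#' The number of interaction terms needed to describe all subsets of two or
#' more species among `n_species` is
#' \deqn{\sum_{k \ge 2} \binom{n}{k} = 2^n - n - 1,}
#' which overflows double precision already at modest community sizes
#' (for 100 species it is of order 10^30). The count is therefore computed
#' exactly in decimal big-integer arithmetic by repeated doubling.
#'
#' @param n_species Number of species (positive integer).
#' @return A list with `count` (exact decimal string), `digits` (number of
#'   decimal digits) and `log10` (base-10 logarithm, as a double).
#' @export
count_interaction_terms <- function(n_species) {
  stopifnot(n_species >= 2, n_species %% 1 == 0)
  # digits little-endian, one decimal digit per element
  d <- c(1L)
  for (i in seq_len(n_species)) d <- bigint_double(d)
  d <- bigint_subtract_small(d, n_species + 1)
  digits <- rev(d)
  str <- paste(digits, collapse = "")
  list(count = str,
       digits = length(d),
       log10 = (length(d) - 1) +
         log10(as.numeric(paste(utils::head(digits, 15), collapse = "")) /
                 10^14))
}

bigint_double <- function(d) {
  d <- d * 2L
  carry <- 0L
  for (i in seq_along(d)) {
    v <- d[i] + carry
    d[i] <- v %% 10L
    carry <- v %/% 10L
  }
  while (carry > 0L) {
    d <- c(d, carry %% 10L)
    carry <- carry %/% 10L
  }
  d
}

bigint_subtract_small <- function(d, m) {
  # subtract a small non-negative integer m from big integer d (d >= m)
  i <- 1L
  m <- as.integer(m)
  while (m > 0L) {
    take <- m %% 10L
    m <- m %/% 10L
    d[i] <- d[i] - take
    if (d[i] < 0L) {
      d[i] <- d[i] + 10L
      m <- m + 1L
    }
    i <- i + 1L
  }
  while (length(d) > 1L && d[length(d)] == 0L) d <- d[-length(d)]
  d
}
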