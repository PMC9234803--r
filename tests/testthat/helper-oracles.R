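# Independent brute-force oracles used to check the package's statistics.
# Each one recomputes the quantity by direct enumeration or an independent
# base-R route, never by calling the implementation under test.

# Exact permutation p for a 2x2 table with both margins fixed:
# enumerate every admissible table, weight by the (central) hypergeometric
# probability, sum the weights of tables whose Pearson statistic is at least
# the observed one.
oracle_chisq_2x2_exact <- function(tab) {
  stopifnot(all(dim(tab) == c(2L, 2L)))
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  stat <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  obs <- stat(tab)
  lo <- max(0L, rs[1L] - cs[2L]); hi <- min(rs[1L], cs[1L])
  p <- 0
  for (a in lo:hi) {
    m <- matrix(c(a, rs[1L] - a, cs[1L] - a, rs[2L] - cs[1L] + a), 2L, 2L)
    if (stat(m) >= obs - 1e-9) p <- p + stats::dhyper(a, cs[1L], cs[2L], rs[1L])
  }
  min(1, p)
}

# Exhaustive permutation p for the rank-sum statistic of sample `a` against
# `b` (two-sided, distance from the null mean), enumerating every assignment
# of the pooled values.
oracle_ranksum_exact <- function(a, b) {
  na <- length(a); N <- na + length(b)
  r <- rank(c(a, b))
  mu <- na * (N + 1) / 2
  obs <- abs(sum(r[seq_len(na)]) - mu)
  idx <- utils::combn(N, na)
  w <- colSums(matrix(r[idx], nrow = na))
  mean(abs(w - mu) >= obs - 1e-9)
}

# Exhaustive permutation p for the (tie-corrected) Kruskal-Wallis statistic,
# using stats::kruskal.test as the independent statistic route. groups is an
# integer vector of group labels aligned with values.
oracle_kw_exact <- function(values, groups) {
  obs <- stats::kruskal.test(values, factor(groups))$statistic
  perms <- all_permutations(seq_along(values))
  stats_perm <- apply(perms, 1L, function(ix) {
    stats::kruskal.test(values[ix], factor(groups))$statistic
  })
  mean(stats_perm >= obs - 1e-9)
}

all_permutations <- function(x) {
  if (length(x) == 1L) return(matrix(x, 1L, 1L))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- all_permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

# Brute-force binomial lower tail by direct summation of the pmf.
oracle_binom_lower <- function(k, n, p) {
  sum(vapply(0:k, function(i) choose(n, i) * p^i * (1 - p)^(n - i),
             numeric(1L)))
}

complement_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[[b]]
}
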