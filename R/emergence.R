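# Rank-based comparisons of time-to-emergence across conditions.
#
# All procedures are implemented from the rank formulas with mid-ranks for
# ties and the standard tie corrections; they depend only on the ordering of
# the day values, so any strictly monotone transform of the days leaves every
# statistic unchanged. Censored lines (never evolved within the horizon) are
# excluded from rank tests and reported separately via evolved_percentage():
# day-of-emergence is only defined for lines that evolved.

#' Construct a time-to-emergence sample
#'
#' @param condition condition name.
#' @param days emergence days of the evolved lines (positive, at most
#'   `horizon`).
#' @param n_censored number of replicate lines that never evolved within the
#'   horizon.
#' @param horizon censoring horizon in days (default 42 = six weeks).
#' @return object of class `emergence_sample`.
#' @export
emergence_sample <- function(condition, days, n_censored = 0L, horizon = 42) {
  days <- as.numeric(days)
  stopifnot(all(days > 0), all(days <= horizon), n_censored >= 0L)
  structure(list(condition = as.character(condition), days = days,
                 n_censored = as.integer(n_censored), horizon = horizon),
            class = "emergence_sample")
}

#' Percentage of replicate lines evolving within the horizon
#'
#' @param sample an [emergence_sample()].
#' @return list with `n_evolved`, `n_censored`, `value` (percentage) and
#'   `percent` (rendered to two decimal places, e.g. `"95.65%"`).
#' @examples
#' evolved_percentage(emergence_sample("Lag", rep(5, 22), n_censored = 1))
#' @export
evolved_percentage <- function(sample) {
  stopifnot(inherits(sample, "emergence_sample"))
  n_ev <- length(sample$days)
  n_total <- n_ev + sample$n_censored
  if (n_total == 0L) {
    stop("empty sample: no evolved and no censored lines", call. = FALSE)
  }
  value <- 100 * n_ev / n_total
  list(n_evolved = n_ev, n_censored = sample$n_censored,
       value = value, percent = render_percent(value / 100, 2L))
}

# Tie bookkeeping shared by all rank tests: mid-ranks and sum(t^3 - t) over
# tie groups of the pooled values.
#' @keywords internal
.rank_ties <- function(pooled) {
  r <- rank(pooled)           # mid-ranks
  t <- table(pooled)
  list(ranks = r, tie_sum = sum(t^3 - t), n = length(pooled))
}

#' @keywords internal
.rank_result <- function(test, statistic, p, tie_correction, df = NA_integer_,
                         z = NA_real_, extra = list()) {
  structure(c(list(test = test, statistic = statistic, p = p,
                   tie_correction = tie_correction, df = df, z = z), extra),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat("<rank_test> ", x$test,
      ": statistic = ", format(x$statistic, digits = 5),
      if (!is.na(x$df)) paste0(", df = ", x$df),
      if (!is.na(x$z)) paste0(", z = ", format(x$z, digits = 4)),
      ", p = ", format(x$p, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @keywords internal
.sample_days <- function(samples) {
  stopifnot(length(samples) >= 2L,
            all(vapply(samples, inherits, logical(1L), "emergence_sample")))
  days <- lapply(samples, `[[`, "days")
  names(days) <- vapply(samples, `[[`, character(1L), "condition")
  if (any(lengths(days) == 0L)) {
    stop("every group must contain at least one evolved line", call. = FALSE)
  }
  days
}

#' Kruskal-Wallis omnibus test on emergence days
#'
#' H statistic computed from pooled mid-ranks,
#' `H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2`, divided by the tie
#' correction `1 - sum(t^3 - t)/(N^3 - N)`; the p-value comes from the
#' chi-square distribution with `groups - 1` degrees of freedom. When all
#' pooled observations are identical the statistic is 0 and p is 1 by
#' convention (the tie correction degenerates to 0).
#'
#' @param samples list of [emergence_sample()] objects (censored lines are
#'   not ranked).
#' @return a `rank_test` with `statistic` (tie-corrected H), `df`, `p` and
#'   `tie_correction`.
#' @export
kruskal_wallis <- function(samples) {
  days <- .sample_days(samples)
  pooled <- unlist(days, use.names = FALSE)
  rt <- .rank_ties(pooled)
  N <- rt$n
  grp <- rep(seq_along(days), lengths(days))
  mean_ranks <- tapply(rt$ranks, grp, mean)
  n_i <- lengths(days)
  H <- 12 / (N * (N + 1)) * sum(n_i * (mean_ranks - (N + 1) / 2)^2)
  C <- 1 - rt$tie_sum / (N^3 - N)
  df <- length(days) - 1L
  if (C <= 0) {  # all observations identical
    return(.rank_result("kruskal_wallis", 0, 1, 1, df = df))
  }
  Hc <- H / C
  .rank_result("kruskal_wallis", Hc,
               stats::pchisq(Hc, df = df, lower.tail = FALSE), C, df = df)
}

#' Dunn's pairwise rank comparison
#'
#' Post-hoc z test between two groups using ranks pooled over *all* groups:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) *
#' (1/n_i + 1/n_j))`, two-sided p from the standard normal. With no ties the
#' tie term vanishes and the textbook form is recovered. z is antisymmetric
#' in (i, j). P-value adjustment across the `k(k-1)/2` pairs is off by
#' default — whether to adjust is a study-level choice — with Bonferroni and
#' Benjamini-Hochberg available via `adjust` when all pairs are computed.
#'
#' @param samples list of [emergence_sample()] objects.
#' @param i,j indices or condition names of the two groups to compare; omit
#'   both to get every pair.
#' @param adjust `"none"` (default), `"bonferroni"` or `"BH"`; applied across
#'   all pairs (only meaningful when computing all pairs).
#' @return for a single pair, a `rank_test` with `z`, `p`, `tie_correction`;
#'   for all pairs, a list with `z` and `p` matrices and `tie_correction`.
#' @export
dunn_pairwise <- function(samples, i = NULL, j = NULL,
                          adjust = c("none", "bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  days <- .sample_days(samples)
  k <- length(days)
  pooled <- unlist(days, use.names = FALSE)
  rt <- .rank_ties(pooled)
  N <- rt$n
  grp <- rep(seq_along(days), lengths(days))
  mean_ranks <- tapply(rt$ranks, grp, mean)
  n_i <- lengths(days)
  var_term <- N * (N + 1) / 12 - rt$tie_sum / (12 * (N - 1))
  C <- 1 - rt$tie_sum / (N^3 - N)

  zval <- function(a, b) {
    if (var_term <= 0) return(0)
    (mean_ranks[[a]] - mean_ranks[[b]]) /
      sqrt(var_term * (1 / n_i[[a]] + 1 / n_i[[b]]))
  }

  resolve <- function(x) {
    if (is.character(x)) match(x, names(days)) else as.integer(x)
  }

  if (!is.null(i) || !is.null(j)) {
    stopifnot(!is.null(i), !is.null(j))
    a <- resolve(i); b <- resolve(j)
    stopifnot(!is.na(a), !is.na(b), a != b)
    z <- zval(a, b)
    p <- if (var_term <= 0) 1 else 2 * stats::pnorm(-abs(z))
    if (adjust == "bonferroni") p <- min(1, p * k * (k - 1) / 2)
    return(.rank_result("dunn_pairwise", z, p, C, z = z,
                        extra = list(pair = names(days)[c(a, b)])))
  }

  zmat <- matrix(0, k, k, dimnames = list(names(days), names(days)))
  for (a in seq_len(k - 1L)) for (b in seq(a + 1L, k)) {
    zmat[a, b] <- zval(a, b)
    zmat[b, a] <- -zmat[a, b]
  }
  pvec <- 2 * stats::pnorm(-abs(zmat[upper.tri(zmat)]))
  if (var_term <= 0) pvec[] <- 1
  pvec <- stats::p.adjust(pvec, method = switch(adjust, none = "none",
                                                bonferroni = "bonferroni",
                                                BH = "BH"))
  pmat <- matrix(NA_real_, k, k, dimnames = dimnames(zmat))
  pmat[upper.tri(pmat)] <- pvec
  pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
  list(test = "dunn_pairwise", z = zmat, p = pmat, tie_correction = C,
       adjust = adjust)
}

#' Wilcoxon rank-sum test between two conditions
#'
#' Two-sample rank-sum comparison (Mann-Whitney), the "Wilcoxon test" for
#' between-strain contrasts. The statistic is the rank sum `W` of the first
#' sample under pooled mid-ranks. Two modes:
#'
#' * exact (default when `n_a + n_b <= 12`, or forced with `exact = TRUE`):
#'   the permutation distribution of `W` is enumerated over all
#'   `choose(n_a + n_b, n_a)` assignments of the pooled values — ties are
#'   handled exactly — and the two-sided p is the probability of a rank sum
#'   at least as far from its mean as observed;
#' * normal approximation: `z = (W - n_a(N+1)/2) / sd`, with tie-corrected
#'   variance `n_a n_b / 12 * ((N+1) - sum(t^3 - t)/(N(N-1)))`, no continuity
#'   correction, two-sided p.
#'
#' @param a,b numeric vectors of emergence days (or [emergence_sample()]
#'   objects).
#' @param exact force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   `NULL` picks it automatically for `n_a + n_b <= 12`.
#' @return a `rank_test` with `statistic` (rank sum of `a`), `p`,
#'   `tie_correction` and `mode`.
#' @export
wilcoxon_ranksum <- function(a, b, exact = NULL) {
  if (inherits(a, "emergence_sample")) a <- a$days
  if (inherits(b, "emergence_sample")) b <- b$days
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  rt <- .rank_ties(pooled)
  W <- sum(rt$ranks[seq_len(na)])
  C <- if (N^3 - N > 0) 1 - rt$tie_sum / (N^3 - N) else 1
  if (is.null(exact)) exact <- N <= 12L

  if (exact) {
    mu <- na * (N + 1) / 2
    idx <- utils::combn(N, na)
    wdist <- colSums(matrix(rt$ranks[idx], nrow = na))
    p <- mean(abs(wdist - mu) >= abs(W - mu) - 1e-9)
    return(.rank_result("wilcoxon_ranksum", W, p, C,
                        extra = list(mode = "exact")))
  }

  mu <- na * (N + 1) / 2
  v <- na * nb / 12 * ((N + 1) - rt$tie_sum / (N * (N - 1)))
  if (v <= 0) {  # all observations identical
    return(.rank_result("wilcoxon_ranksum", W, 1, C,
                        extra = list(mode = "normal")))
  }
  z <- (W - mu) / sqrt(v)
  .rank_result("wilcoxon_ranksum", W, 2 * stats::pnorm(-abs(z)), C, z = z,
               extra = list(mode = "normal"))
}
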