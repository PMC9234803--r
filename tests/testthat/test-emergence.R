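test_that("evolved percentages render to two decimals", {
  lag <- emergence_sample("Lag", days = rep(5, 22), n_censored = 1L)
  ep <- evolved_percentage(lag)
  expect_equal(ep$value, 100 * 22 / 23)
  expect_equal(ep$percent, "95.65%")

  ar2 <- emergence_sample("AR2", days = rep(4, 21), n_censored = 0L)
  expect_equal(evolved_percentage(ar2)$percent, "100.00%")

  none <- emergence_sample("dead", days = numeric(0), n_censored = 10L)
  expect_equal(evolved_percentage(none)$percent, "0.00%")

  expect_error(evolved_percentage(emergence_sample("x", numeric(0), 0L)),
               "empty")
  expect_error(emergence_sample("x", days = c(5, 50)))  # beyond horizon
})

test_that("Kruskal-Wallis matches the independent implementation, ties included", {
  set.seed(21)
  for (rep_i in 1:6) {
    days <- list(sample(1:6, 8, replace = TRUE),   # heavy ties
                 sample(1:6, 7, replace = TRUE),
                 rexp(9, 0.3) + 0.5)
    samples <- mapply(function(d, nm) emergence_sample(nm, pmin(d, 42)),
                      days, c("a", "b", "c"), SIMPLIFY = FALSE)
    got <- kruskal_wallis(samples)
    want <- kruskal.test(unlist(days), rep(1:3, lengths(days)))
    expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-12)
    expect_equal(got$p, want$p.value, tolerance = 1e-12)
    expect_equal(got$df, 2L)
  }
  # identical groups: zero statistic; identical constant values: p = 1
  same <- list(emergence_sample("a", c(1, 2, 3)),
               emergence_sample("b", c(1, 2, 3)))
  expect_equal(kruskal_wallis(same)$statistic, 0, tolerance = 1e-12)
  const <- list(emergence_sample("a", c(2, 2)), emergence_sample("b", c(2, 2)))
  expect_equal(kruskal_wallis(const)$p, 1)
})

test_that("exact permutation p of the H statistic matches exhaustive enumeration", {
  # N <= 8 so all N! relabellings can be enumerated
  values <- c(1.2, 3.4, 2.2, 5.1, 4.4, 0.7, 3.4)  # includes a tie
  groups <- c(1L, 1L, 2L, 2L, 3L, 3L, 3L)
  p_oracle <- oracle_kw_exact(values, groups)

  samples <- lapply(1:3, function(g) {
    emergence_sample(paste0("g", g), values[groups == g])
  })
  obs <- kruskal_wallis(samples)$statistic
  # permutation distribution of our statistic
  perms <- all_permutations(seq_along(values))
  stats_perm <- apply(perms, 1L, function(ix) {
    s <- lapply(1:3, function(g) {
      emergence_sample(paste0("g", g), values[ix][groups == g])
    })
    kruskal_wallis(s)$statistic
  })
  expect_equal(mean(stats_perm >= obs - 1e-9), p_oracle, tolerance = 1e-12)
})

test_that("Dunn z follows the pooled-rank formula and its identities", {
  s <- list(emergence_sample("a", c(2, 4, 4, 9)),
            emergence_sample("b", c(1, 3, 7)),
            emergence_sample("c", c(5, 6, 8, 10, 11)))
  ij <- dunn_pairwise(s, "a", "b")
  ji <- dunn_pairwise(s, "b", "a")
  expect_equal(ij$z, -ji$z)               # antisymmetry
  expect_equal(ij$p, ji$p)

  allp <- dunn_pairwise(s)
  expect_equal(allp$z["a", "b"], ij$z)
  expect_equal(allp$z, -t(allp$z))
  expect_equal(allp$p["a", "b"], ij$p)

  # equal mean ranks => z = 0, p = 1
  eq <- list(emergence_sample("a", c(1, 4)), emergence_sample("b", c(2, 3)))
  d0 <- dunn_pairwise(eq, "a", "b")
  expect_equal(d0$z, 0)
  expect_equal(d0$p, 1)

  # two groups, no ties: z^2 equals the Kruskal-Wallis statistic
  set.seed(5)
  a <- rexp(6, 0.4) + 0.1
  b <- rexp(8, 0.4) + 0.1
  two <- list(emergence_sample("a", a), emergence_sample("b", b))
  z <- dunn_pairwise(two, "a", "b")$z
  H <- kruskal_wallis(two)$statistic
  expect_equal(z^2, H, tolerance = 1e-10)

  # no ties: the tie term vanishes and the textbook form is recovered
  r <- rank(c(a, b))
  N <- length(r)
  z_textbook <- (mean(r[1:6]) - mean(r[7:14])) /
    sqrt(N * (N + 1) / 12 * (1 / 6 + 1 / 8))
  expect_equal(z, z_textbook, tolerance = 1e-12)

  # Bonferroni inflates the single-pair p by the number of pairs
  padj <- dunn_pairwise(s, "a", "b", adjust = "bonferroni")$p
  expect_equal(padj, min(1, ij$p * 3))
})

test_that("rank-sum exact mode equals exhaustive enumeration; normal mode tracks it", {
  set.seed(8)
  for (rep_i in 1:5) {
    a <- sample(1:9, 5, replace = TRUE)
    b <- sample(1:9, 6, replace = TRUE)
    got <- wilcoxon_ranksum(a, b)          # N = 11 <= 12: exact mode
    expect_equal(got$mode, "exact")
    expect_equal(got$p, oracle_ranksum_exact(a, b), tolerance = 1e-12)
    # tie-free case also agrees with the classic exact distribution
    a2 <- rexp(5); b2 <- rexp(6)
    got2 <- wilcoxon_ranksum(a2, b2)
    want2 <- wilcox.test(a2, b2, exact = TRUE)$p.value
    expect_equal(got2$p, want2, tolerance = 1e-12)
    # normal approximation within 0.02 of exact in the significance region
    # (exact p below ~0.1; shifted samples put every draw there); in the
    # mid-range the 12-observation rank distribution is too coarse for a
    # tighter bound, so only the decision-relevant tail is held to 0.02
    a3 <- rexp(6); b3 <- rexp(6) + 2.5
    pe <- wilcoxon_ranksum(a3, b3, exact = TRUE)$p
    pn <- wilcoxon_ranksum(a3, b3, exact = FALSE)$p
    if (pe <= 0.11) expect_lt(abs(pn - pe), 0.02 + 1e-9)
  }
  # overall the approximation never strays far at n = 6 + 6
  set.seed(77)
  devs <- replicate(200, {
    a <- rexp(6); b <- rexp(6)
    abs(wilcoxon_ranksum(a, b, exact = TRUE)$p -
          wilcoxon_ranksum(a, b, exact = FALSE)$p)
  })
  expect_lt(max(devs), 0.08)
  expect_lt(mean(devs), 0.06)
  # identical multisets: exact p = 1
  expect_equal(wilcoxon_ranksum(c(1, 2, 3), c(3, 1, 2))$p, 1)
})

test_that("rank procedures are invariant under strictly monotone transforms", {
  set.seed(13)
  days <- list(rexp(7, 0.5) + 0.2, rexp(6, 0.3) + 0.2, rexp(8, 0.4) + 0.2)
  f <- function(x) log1p(x)^3  # strictly increasing
  mk <- function(d) {
    list(raw = lapply(seq_along(d), function(i) {
           emergence_sample(paste0("g", i), d[[i]])
         }),
         tr = lapply(seq_along(d), function(i) {
           emergence_sample(paste0("g", i), f(d[[i]]))
         }))
  }
  s <- mk(days)
  expect_equal(kruskal_wallis(s$raw)$statistic,
               kruskal_wallis(s$tr)$statistic, tolerance = 1e-12)
  expect_equal(dunn_pairwise(s$raw, 1, 2)$z, dunn_pairwise(s$tr, 1, 2)$z,
               tolerance = 1e-12)
  expect_equal(wilcoxon_ranksum(days[[1]], days[[2]])$p,
               wilcoxon_ranksum(f(days[[1]]), f(days[[2]]))$p,
               tolerance = 1e-12)
})

test_that("type-I error sits at the nominal level under the null", {
  # two groups of 15 lines drawn from one emergence-time distribution;
  # the exact rejection rate of the normal-approximation rank-sum test at
  # alpha = 0.05 with these sizes is 0.0502, so the empirical rate over
  # 3000 datasets must land inside the 99% binomial band around 0.05
  n_sim <- 3000L
  set.seed(1701)
  rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    a <- rexp(15, 0.4)
    b <- rexp(15, 0.4)
    rej[i] <- wilcoxon_ranksum(a, b, exact = FALSE)$p < 0.05
  }
  half_width <- qnorm(0.995) * sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(mean(rej) - 0.05), half_width)
})
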