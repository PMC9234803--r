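fx <- study_fixtures()

test_that("spectrum construction respects the categorization policy", {
  ar2 <- build_spectrum(fx$records$AR2, categorization_policy("mutation"))
  expect_equal(sort(ar2$categories), c("ntrB:A289C", "ntrB:T326C"))
  expect_equal(ar2$counts["AR2", "ntrB:A289C"], 20L)
  expect_equal(ar2$counts["AR2", "ntrB:T326C"], 1L)

  ar2g <- build_spectrum(fx$records$AR2, categorization_policy("gene"))
  expect_equal(ar2g$categories, "ntrB")
  expect_equal(unname(ar2g$counts["AR2", ]), 21L)

  mg <- build_spectrum(fx$records$mutS, categorization_policy("gene"))
  expect_equal(mg$counts["mutS", "ntrB"], 12L)
  expect_equal(mg$counts["mutS", "glnK"], 3L)
  expect_equal(mg$counts["mutS", "unidentified"], 5L)

  mg2 <- build_spectrum(fx$records$mutS,
                        categorization_policy("gene",
                                              include_unidentified = FALSE))
  expect_false("unidentified" %in% mg2$categories)
  expect_equal(sum(mg2$counts), 15L)

  # row sums equal contributing lines; no all-zero columns
  both <- build_spectrum(rbind(fx$records$AR2, fx$records$mutS))
  expect_equal(unname(rowSums(both$counts)[c("AR2", "mutS")]), c(21L, 20L))
  expect_true(all(colSums(both$counts) > 0L))

  censored <- fx$records$AR2
  censored$evolved[1] <- FALSE
  expect_error(build_spectrum(censored), "evolved")
})

test_that("pooling rare categories conserves total counts", {
  sp0 <- build_spectrum(fx$records$mutS, categorization_policy("mutation"))
  sp <- build_spectrum(fx$records$mutS,
                       categorization_policy("mutation", pool_below = 2L))
  expect_equal(sum(sp$counts), sum(sp0$counts))
  expect_true("other" %in% sp$categories)
  # categories with total >= 2 survive: A289C (7), A608G (2), unidentified (5)
  expect_true(all(c("ntrB:A289C", "ntrB:A608G", "unidentified")
                  %in% sp$categories))
  expect_equal(sp$counts["mutS", "other"], 6L)
})

test_that("hotspot fractions render the published percentages", {
  sp <- build_spectrum(rbind(fx$records$AR2, fx$records$mutS))
  ar2 <- hotspot_fraction(sp, "AR2", "ntrB:A289C")
  expect_equal(ar2$fraction, 20 / 21)
  expect_equal(ar2$percent, "95.2%")
  muts <- hotspot_fraction(sp, "mutS", "ntrB:A289C")
  expect_equal(muts$fraction, 7 / 20)
  expect_equal(muts$percent, "35.0%")
  absent <- hotspot_fraction(sp, "AR2", "glnA:Q1X")
  expect_equal(absent$fraction, 0)
  expect_equal(absent$percent, "0.0%")
  expect_error(hotspot_fraction(sp, "nope", "ntrB:A289C"), "condition")
})

test_that("Pearson comparison matches the independent chi-square route", {
  # hand-checkable 2x2: hotspot vs rest for the ancestral and relocated lines
  tab <- matrix(c(20L, 1L, 11L, 11L), nrow = 2L, byrow = TRUE,
                dimnames = list(c("x", "y"), c("hot", "rest")))
  sp <- structure(list(counts = tab, conditions = rownames(tab),
                       categories = colnames(tab),
                       policy = categorization_policy()),
                  class = "spectrum_table")
  cmp <- compare_spectra(sp, "x", "y", method = "both",
                         n_resamples = 50000L, seed = 7L)
  oracle <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(cmp$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(cmp$statistic, 10.93, tolerance = 1e-3)
  expect_equal(cmp$df, 1L)
  expect_equal(cmp$p_asymptotic, oracle$p.value, tolerance = 1e-12)
  expect_equal(cmp$p_asymptotic, 9.5e-4, tolerance = 0.01)

  # identical rows: zero statistic, p = 1
  tab2 <- matrix(c(5L, 5L, 5L, 5L), 2L, dimnames = list(c("a", "b"), NULL))
  sp2 <- structure(list(counts = tab2, conditions = c("a", "b"),
                        categories = c("c1", "c2"),
                        policy = categorization_policy()),
                   class = "spectrum_table")
  cmp2 <- compare_spectra(sp2, "a", "b", method = "both",
                          n_resamples = 1000L, seed = 1L)
  expect_equal(cmp2$statistic, 0)
  expect_equal(cmp2$p_asymptotic, 1)
  expect_equal(cmp2$p_montecarlo, 1)
})

test_that("comparison is symmetric and flags sparse tables", {
  sp <- build_spectrum(rbind(fx$records$AR2, fx$records$mutS))
  ab <- compare_spectra(sp, "AR2", "mutS", n_resamples = 5000L, seed = 3L)
  ba <- compare_spectra(sp, "mutS", "AR2", n_resamples = 5000L, seed = 3L)
  expect_equal(ab$statistic, ba$statistic)
  expect_equal(ab$p_asymptotic, ba$p_asymptotic)
  expect_equal(ab$p_montecarlo, ba$p_montecarlo)
  expect_true(ab$mc_recommended)
  expect_equal(ab$df, ncol(ab$table) - 1L)

  one_cat <- build_spectrum(fx$records$AR2[fx$records$AR2$mutation == "A289C", ])
  expect_error(compare_spectra(one_cat, "AR2", "AR2"), "condition|degenerate")
})

test_that("Monte-Carlo p tracks the exact permutation p, which tracks the
           asymptotic p, on well-filled tables", {
  tab <- matrix(c(30L, 20L, 18L, 32L), nrow = 2L, byrow = TRUE,
                dimnames = list(c("a", "b"), c("c1", "c2")))
  sp <- structure(list(counts = tab, conditions = c("a", "b"),
                       categories = c("c1", "c2"),
                       policy = categorization_policy()),
                  class = "spectrum_table")
  B <- 40000L
  cmp <- compare_spectra(sp, "a", "b", method = "both",
                         n_resamples = B, seed = 5L)
  expect_false(cmp$mc_recommended)  # all expected counts >= 5
  # the Monte-Carlo estimate converges to the fixed-margin permutation p
  p_exact <- oracle_chisq_2x2_exact(tab)
  se <- sqrt(p_exact * (1 - p_exact) / B)
  expect_lt(abs(cmp$p_montecarlo - p_exact), 3 * se + 2 / B)
  # and the permutation p is itself close to the chi-square approximation
  # (they differ by the residual discreteness of a 100-line table)
  expect_lt(abs(cmp$p_asymptotic - p_exact), 0.02)
})

test_that("Monte-Carlo p converges to the exact permutation p on small 2x2", {
  tabs <- list(matrix(c(6L, 2L, 1L, 7L), 2L, byrow = TRUE),
               matrix(c(3L, 5L, 4L, 4L), 2L, byrow = TRUE),
               matrix(c(1L, 7L, 6L, 2L), 2L, byrow = TRUE))
  for (tab in tabs) {
    dimnames(tab) <- list(c("a", "b"), c("c1", "c2"))
    sp <- structure(list(counts = tab, conditions = c("a", "b"),
                         categories = c("c1", "c2"),
                         policy = categorization_policy()),
                    class = "spectrum_table")
    B <- 60000L
    cmp <- compare_spectra(sp, "a", "b", method = "montecarlo",
                           n_resamples = B, seed = 11L)
    p_exact <- oracle_chisq_2x2_exact(tab)
    se <- sqrt(p_exact * (1 - p_exact) / B)
    expect_lt(abs(cmp$p_montecarlo - p_exact), 3 * se + 2 / B)
    expect_gt(cmp$p_montecarlo, 0)  # add-one rule
    expect_lte(cmp$p_montecarlo, 1)
  }
})

test_that("spectrum tables serialize to CSV and back", {
  sp <- build_spectrum(rbind(fx$records$AR2, fx$records$mutS))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_spectrum_csv(sp, path)
  back <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  expect_equal(as.matrix(back)[rownames(sp$counts), colnames(sp$counts)],
               sp$counts)
})
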