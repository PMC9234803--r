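# Mutation spectra per condition and their chi-square comparison.

#' Categorization policy for spectrum construction
#'
#' How replicate-line outcomes are mapped to spectrum categories:
#'
#' * `level = "mutation"`: categories are `"gene:mutation"` (canonical label),
#'   so distinct mutations within one gene are separate categories;
#' * `level = "gene"`: categories are gene names, pooling all mutations in a
#'   locus — the locus-level view used when asking whether the mutational
#'   *target* rather than the precise change differs between conditions.
#'
#' Lines whose adaptive mutation was never located form their own
#' `"unidentified"` category when `include_unidentified = TRUE` (they are a
#' real slice of the spectrum — a quarter of the mutator lines in the
#' motivating dataset) and are dropped otherwise. Categories with fewer than
#' `pool_below` counts in total are pooled into `"other"`; `0` disables
#' pooling. Pooling conserves total counts.
#'
#' @param level `"mutation"` or `"gene"`.
#' @param pool_below minimum total count below which a category is pooled
#'   into `"other"` (default 0 = no pooling).
#' @param include_unidentified keep unidentified lines as a category?
#' @return an object of class `categorization_policy`.
#' @export
categorization_policy <- function(level = c("mutation", "gene"),
                                  pool_below = 0L,
                                  include_unidentified = TRUE) {
  level <- match.arg(level)
  stopifnot(length(pool_below) == 1L, pool_below >= 0,
            is.logical(include_unidentified))
  structure(list(level = level,
                 pool_below = as.integer(pool_below),
                 include_unidentified = include_unidentified),
            class = "categorization_policy")
}

#' Build a mutation spectrum table
#'
#' Tallies evolved replicate lines into categories per condition (strain)
#' under a [categorization_policy()]. Every record must belong to an evolved
#' line: censored lines carry no mutation and have no place in a spectrum.
#' Row sums equal the number of contributing lines per condition, and no
#' all-zero category columns survive construction.
#'
#' @param records mutation-record data frame (evolved lines only).
#' @param policy a [categorization_policy()].
#' @return object of class `spectrum_table`: list with `counts` (integer
#'   matrix, conditions x categories), `conditions`, `categories`, `policy`.
#' @examples
#' fx <- study_fixtures()
#' build_spectrum(fx$records$AR2, categorization_policy("mutation"))
#' @export
build_spectrum <- function(records, policy = categorization_policy()) {
  records <- validate_records(records)
  stopifnot(inherits(policy, "categorization_policy"))
  if (any(!records$evolved)) {
    stop("spectrum records must all be evolved lines; found ",
         sum(!records$evolved), " censored record(s)", call. = FALSE)
  }

  unid <- !records$identified | records$gene == "unidentified"
  if (!policy$include_unidentified) records <- records[!unid, , drop = FALSE]
  unid <- !records$identified | records$gene == "unidentified"

  category <- character(nrow(records))
  category[unid] <- "unidentified"
  idr <- records[!unid, , drop = FALSE]
  if (nrow(idr) > 0L) {
    category[!unid] <- if (policy$level == "gene") {
      idr$gene
    } else {
      canon <- vapply(idr$mutation, function(l) {
        if (nzchar(l)) format(parse_mutation_label(l)) else "unspecified"
      }, character(1L), USE.NAMES = FALSE)
      paste(idr$gene, canon, sep = ":")
    }
  }

  counts <- table(factor(records$strain), factor(category))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = unname(dimnames(counts)))

  if (policy$pool_below > 0L) {
    small <- colSums(counts) < policy$pool_below
    if (any(small) && sum(!small) >= 1L) {
      pooled <- cbind(counts[, !small, drop = FALSE],
                      other = rowSums(counts[, small, drop = FALSE]))
      stopifnot(sum(pooled) == sum(counts))  # count conservation
      counts <- pooled
    }
  }
  counts <- counts[, colSums(counts) > 0L, drop = FALSE]

  structure(list(counts = counts,
                 conditions = rownames(counts),
                 categories = colnames(counts),
                 policy = policy),
            class = "spectrum_table")
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat("<spectrum_table> level=", x$policy$level,
      if (x$policy$pool_below > 0L) paste0(" pool_below=", x$policy$pool_below),
      "\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' @export
as.data.frame.spectrum_table <- function(x, ...) {
  as.data.frame.matrix(x$counts)
}

#' Write a spectrum table to CSV (conditions as rows, categories as columns)
#'
#' @param spectrum a `spectrum_table`.
#' @param path output file path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "spectrum_table"))
  utils::write.csv(as.data.frame(spectrum), path, fileEncoding = "UTF-8")
  invisible(path)
}

#' Hotspot fraction of a condition's spectrum
#'
#' The potency of a mutational hotspot in one condition: the proportion of
#' that condition's evolved lines whose adaptive mutation falls in the
#' hotspot category. An absent category gives fraction 0; a condition with no
#' lines is an error (the fraction is undefined).
#'
#' @param spectrum a [build_spectrum()] result.
#' @param condition condition (row) name.
#' @param category hotspot category label, e.g. `"ntrB:A289C"`.
#' @return list with `count`, `total`, `fraction` and `percent` (rendered to
#'   one decimal place, the convention for spectrum fractions).
#' @examples
#' fx <- study_fixtures()
#' sp <- build_spectrum(fx$records$AR2)
#' hotspot_fraction(sp, "AR2", "ntrB:A289C")$percent  # "95.2%"
#' @export
hotspot_fraction <- function(spectrum, condition, category) {
  stopifnot(inherits(spectrum, "spectrum_table"))
  if (!condition %in% spectrum$conditions) {
    stop("unknown condition: ", sQuote(condition), call. = FALSE)
  }
  row <- spectrum$counts[condition, ]
  total <- sum(row)
  if (total == 0L) {
    stop("hotspot fraction undefined: no lines for condition ",
         sQuote(condition), call. = FALSE)
  }
  count <- if (category %in% spectrum$categories) row[[category]] else 0L
  frac <- count / total
  list(count = as.integer(count), total = as.integer(total),
       fraction = frac, percent = render_percent(frac, 1L))
}

# Pearson chi-square statistic on a contingency table (own implementation;
# the comparison statistic is the package's responsibility, not delegated).
#' @keywords internal
pearson_statistic <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

#' Compare two conditions' mutation spectra
#'
#' Pearson chi-square comparison of two rows of a spectrum table, restricted
#' to their jointly non-zero categories. Two p-values are available:
#'
#' * asymptotic, from the chi-square distribution with `k - 1` degrees of
#'   freedom (`k` = retained categories); unreliable for the sparse tables
#'   typical of evolution experiments, flagged via `mc_recommended` whenever
#'   any expected count falls below 5;
#' * Monte-Carlo, from tables resampled with both margins fixed (random
#'   reassignment of category labels to lines, Patefield algorithm), with the
#'   add-one estimator `p = (1 + #{X2_sim >= X2_obs}) / (n_resamples + 1)`,
#'   which never returns 0.
#'
#' No continuity correction is applied. The comparison is symmetric in the
#' two conditions.
#'
#' @param spectrum a `spectrum_table` containing both conditions.
#' @param a,b condition (row) names.
#' @param method `"asymptotic"`, `"montecarlo"` or `"both"`.
#' @param n_resamples Monte-Carlo resamples (default `1e4`).
#' @param seed RNG seed recorded in the result.
#' @return object of class `spectrum_comparison`: `statistic`, `df`,
#'   `p_asymptotic`, `p_montecarlo` (NA unless requested), `n_resamples`,
#'   `seed`, `mc_recommended`, `table`.
#' @examples
#' fx <- study_fixtures()
#' sp <- build_spectrum(rbind(fx$records$AR2, fx$records$mutS))
#' compare_spectra(sp, "AR2", "mutS", method = "both", seed = 1)
#' @export
compare_spectra <- function(spectrum, a, b,
                            method = c("both", "asymptotic", "montecarlo"),
                            n_resamples = 10000L, seed = 1L) {
  stopifnot(inherits(spectrum, "spectrum_table"))
  method <- match.arg(method)
  missing_cond <- setdiff(c(a, b), spectrum$conditions)
  if (length(missing_cond) > 0L) {
    stop("condition(s) not in spectrum: ",
         paste(sQuote(missing_cond), collapse = ", "), call. = FALSE)
  }
  tab <- spectrum$counts[c(a, b), , drop = FALSE]
  tab <- tab[, colSums(tab) > 0L, drop = FALSE]
  k <- ncol(tab)
  if (k < 2L) {
    stop("degenerate comparison: fewer than 2 jointly non-zero categories",
         call. = FALSE)
  }

  stat <- pearson_statistic(tab)
  df <- k - 1L
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  mc_recommended <- any(expected < 5)
  p_asym <- stats::pchisq(stat, df = df, lower.tail = FALSE)

  p_mc <- NA_real_
  if (method %in% c("montecarlo", "both")) {
    stopifnot(n_resamples >= 1L)
    sims <- with_seed(seed,
      stats::r2dtable(n_resamples, rowSums(tab), colSums(tab)))
    exceed <- sum(vapply(sims, pearson_statistic, numeric(1L))
                  >= stat - 1e-12)
    p_mc <- (1 + exceed) / (n_resamples + 1)
  }

  structure(list(statistic = stat, df = df,
                 p_asymptotic = if (method == "montecarlo") NA_real_ else p_asym,
                 p_montecarlo = p_mc,
                 n_resamples = if (is.na(p_mc)) 0L else as.integer(n_resamples),
                 seed = as.integer(seed),
                 mc_recommended = mc_recommended,
                 conditions = c(a, b), table = tab),
            class = "spectrum_comparison")
}

#' @export
print.spectrum_comparison <- function(x, ...) {
  cat("<spectrum_comparison> ", x$conditions[1L], " vs ", x$conditions[2L],
      "\n  X-squared = ", format(x$statistic, digits = 5),
      ", df = ", x$df, "\n", sep = "")
  if (!is.na(x$p_asymptotic)) {
    cat("  p (asymptotic)  =", format(x$p_asymptotic, digits = 4), "\n")
  }
  if (!is.na(x$p_montecarlo)) {
    cat("  p (Monte-Carlo) =", format(x$p_montecarlo, digits = 4),
        sprintf("[%d resamples, seed %d]\n", x$n_resamples, x$seed))
  }
  if (x$mc_recommended) {
    cat("  note: expected counts < 5; prefer the Monte-Carlo p-value\n")
  }
  invisible(x)
}
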