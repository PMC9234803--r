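# End-to-end orchestration: tables in, reproducible analysis report out.

#' Run the full hotspot-potency analysis
#'
#' Orchestrates every stage over a set of per-condition mutation tables:
#'
#' 1. spectrum construction under one [categorization_policy()];
#' 2. hotspot fraction per condition;
#' 3. pairwise spectrum comparisons (asymptotic and Monte-Carlo chi-square);
#' 4. transition/transversion counts and the transition-omission test per
#'    condition (exact binomial plus bootstrap);
#' 5. rank-based emergence-time comparisons (Kruskal-Wallis, Dunn pairwise),
#'    when per-line days are available.
#'
#' Stages that cannot run (a single condition, no recorded days, no
#' classified substitutions) are skipped with a notice collected in the
#' report, not an error. Re-running with identical inputs, configuration and
#' seed reproduces the report exactly.
#'
#' @param tables inputs, one per condition: a named list whose elements are
#'   mutation-record data frames, CSV paths (read with
#'   [read_mutation_table()]) or fixture names (see [fixture()]); a bare
#'   character vector of fixture names/paths also works.
#' @param hotspot_category hotspot category label at mutation level
#'   (default `"ntrB:A289C"`).
#' @param policy [categorization_policy()] for the spectrum stage.
#' @param titv_tail tail of the transition test (default `"lower"`:
#'   omission of transitions).
#' @param n_resamples resamples for Monte-Carlo comparisons and the
#'   bootstrap transition test.
#' @param seed master seed recorded in the report and used for every
#'   stochastic stage.
#' @param evolved_totals optional data frame (`condition`, `n_evolved`,
#'   `n_total`) for evolved-percentage summaries; defaults to the counts
#'   implied by the tables (censored rows counted per condition).
#' @return object of class `analysis_report`; see [write_report_json()].
#' @examples
#' rep <- run_pipeline(c("AR2", "mutS"), n_resamples = 2000, seed = 1)
#' print(rep)
#' @export
run_pipeline <- function(tables,
                         hotspot_category = "ntrB:A289C",
                         policy = categorization_policy(),
                         titv_tail = "lower",
                         n_resamples = 10000L,
                         seed = 1L,
                         evolved_totals = NULL) {
  if (is.character(tables)) tables <- as.list(tables)
  stopifnot(length(tables) >= 1L)
  notices <- character(0)

  load_one <- function(x) {
    if (is.data.frame(x)) return(validate_records(x))
    stopifnot(is.character(x), length(x) == 1L)
    if (file.exists(x)) read_mutation_table(x) else fixture(x)
  }
  records_list <- lapply(tables, load_one)
  records <- do.call(rbind, c(records_list, list(make.row.names = FALSE)))
  conditions <- unique(records$strain)

  # evolved-percentage summaries
  if (is.null(evolved_totals)) {
    n_ev <- tapply(records$evolved, records$strain, sum)
    n_tot <- tapply(records$evolved, records$strain, length)
    evolved_totals <- data.frame(condition = names(n_ev),
                                 n_evolved = as.integer(n_ev),
                                 n_total = as.integer(n_tot),
                                 stringsAsFactors = FALSE)
  }
  evolved_pct <- lapply(seq_len(nrow(evolved_totals)), function(i) {
    with(evolved_totals[i, ], {
      s <- emergence_sample(condition,
                            days = rep(1, n_evolved),
                            n_censored = n_total - n_evolved)
      c(condition = condition, evolved_percentage(s))
    })
  })
  names(evolved_pct) <- evolved_totals$condition

  # spectrum stage (evolved lines only)
  ev <- records[records$evolved, , drop = FALSE]
  spectrum <- build_spectrum(ev, policy)

  fractions <- lapply(spectrum$conditions, function(cond) {
    hotspot_fraction(spectrum, cond, hotspot_category)
  })
  names(fractions) <- spectrum$conditions

  # pairwise spectrum comparisons
  comparisons <- list()
  if (length(spectrum$conditions) >= 2L) {
    pairs <- utils::combn(spectrum$conditions, 2L, simplify = FALSE)
    comparisons <- lapply(pairs, function(pr) {
      compare_spectra(spectrum, pr[1L], pr[2L], method = "both",
                      n_resamples = n_resamples, seed = seed)
    })
    names(comparisons) <- vapply(pairs, paste, character(1L),
                                 collapse = " vs ")
  } else {
    notices <- c(notices,
                 "single condition: spectrum comparisons skipped")
  }

  # transition/transversion stage
  titv <- lapply(split(ev, ev$strain), function(df) {
    ct <- count_transitions(df)
    if (ct$n_classified == 0L) return(NULL)
    list(counts = ct,
         exact = titv_exact(ct$n_transitions, ct$n_classified,
                            tail = titv_tail),
         bootstrap = titv_bootstrap(ct$n_transitions, ct$n_classified,
                                    tail = titv_tail,
                                    n_resamples = n_resamples, seed = seed))
  })
  skipped <- names(titv)[vapply(titv, is.null, logical(1L))]
  if (length(skipped) > 0L) {
    notices <- c(notices, paste0("no classified substitutions, Ti/Tv test ",
                                 "skipped: ", paste(skipped, collapse = ", ")))
  }
  titv <- titv[!vapply(titv, is.null, logical(1L))]

  # emergence stage (needs per-line days)
  emergence <- NULL
  has_days <- !is.na(ev$day)
  conds_with_days <- unique(ev$strain[has_days])
  if (length(conds_with_days) >= 2L) {
    samples <- lapply(conds_with_days, function(cond) {
      sub <- records[records$strain == cond, , drop = FALSE]
      emergence_sample(cond,
                       days = sub$day[sub$evolved & !is.na(sub$day)],
                       n_censored = sum(!sub$evolved))
    })
    emergence <- list(kruskal_wallis = kruskal_wallis(samples),
                      dunn = dunn_pairwise(samples))
  } else {
    notices <- c(notices,
                 "per-line emergence days unavailable for >=2 conditions: rank tests skipped")
  }

  structure(list(conditions = conditions,
                 policy = policy,
                 spectrum = spectrum,
                 evolved_percentages = evolved_pct,
                 hotspot_category = hotspot_category,
                 hotspot_fractions = fractions,
                 comparisons = comparisons,
                 titv = titv,
                 emergence = emergence,
                 notices = notices,
                 n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed),
                 version = as.character(utils::packageVersion("hotspotr"))),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> hotspotr", x$version, "| seed", x$seed,
      "| resamples", x$n_resamples, "\n")
  cat("conditions:", paste(x$conditions, collapse = ", "), "\n\n")
  cat("evolved percentages:\n")
  for (e in x$evolved_percentages) {
    cat(sprintf("  %-8s %d/%d = %s\n", e$condition, e$n_evolved,
                e$n_evolved + e$n_censored, e$percent))
  }
  cat("\nhotspot fraction (", x$hotspot_category, "):\n", sep = "")
  for (cond in names(x$hotspot_fractions)) {
    f <- x$hotspot_fractions[[cond]]
    cat(sprintf("  %-8s %d/%d = %s\n", cond, f$count, f$total, f$percent))
  }
  if (length(x$comparisons) > 0L) {
    cat("\nspectrum comparisons:\n")
    for (nm in names(x$comparisons)) {
      cmp <- x$comparisons[[nm]]
      cat(sprintf("  %-16s X2 = %.3f, df = %d, p_asym = %.4g, p_mc = %.4g%s\n",
                  nm, cmp$statistic, cmp$df, cmp$p_asymptotic,
                  cmp$p_montecarlo,
                  if (cmp$mc_recommended) "  [sparse: prefer p_mc]" else ""))
    }
  }
  if (length(x$titv) > 0L) {
    cat("\ntransition tests (", x$titv[[1L]]$exact$tail, " tail):\n", sep = "")
    for (cond in names(x$titv)) {
      t <- x$titv[[cond]]
      cat(sprintf("  %-8s %d/%d transitions, p_exact = %.4g, p_boot = %.4g\n",
                  cond, t$counts$n_transitions, t$counts$n_classified,
                  t$exact$p_value, t$bootstrap$p_value))
    }
  }
  if (!is.null(x$emergence)) {
    kw <- x$emergence$kruskal_wallis
    cat(sprintf("\nemergence: Kruskal-Wallis H = %.3f, df = %d, p = %.4g\n",
                kw$statistic, kw$df, kw$p))
  }
  for (n in x$notices) cat("note:", n, "\n")
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' Flattens the report into a plain list (matrices become row-named lists)
#' and writes pretty-printed JSON. Every stochastic result carries its seed
#' and resample count, so the file documents its own reproduction.
#'
#' @param report an `analysis_report` from [run_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  strip <- function(x) {
    if (inherits(x, "spectrum_table")) {
      return(list(policy = unclass(x$policy),
                  counts = as.data.frame(x$counts)))
    }
    if (is.matrix(x)) return(as.data.frame(x))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  jsonlite::write_json(strip(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
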