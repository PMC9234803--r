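# Transition-enrichment/omission test against the 1/3 combinatorial null.
#
# Null model: each point substitution is a transition with probability 1/3,
# because exactly 4 of the 12 ordered base substitutions are transitions
# (each base has one transition partner and two transversion partners) and
# fixation is assumed equally likely regardless of mutation type. Indels and
# unknown classifications never enter n_total: the null is about point
# substitutions only.

#' @keywords internal
.titv_validate <- function(n_obs, n_total, p_transition, tail) {
  stopifnot(length(n_obs) == 1L, length(n_total) == 1L,
            n_total >= 1L, n_obs >= 0L,
            p_transition > 0, p_transition < 1)
  if (n_obs > n_total) {
    stop("n_obs (", n_obs, ") exceeds n_total (", n_total, ")", call. = FALSE)
  }
  match.arg(tail, c("lower", "upper", "two_sided"))
}

#' @keywords internal
.titv_result <- function(n_obs, n_total, tail, p, n_resamples, seed, mode,
                         p_transition) {
  structure(list(n_transitions_observed = as.integer(n_obs),
                 n_total = as.integer(n_total),
                 p_transition = p_transition,
                 tail = tail, p_value = p,
                 n_resamples = as.integer(n_resamples),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 mode = mode),
            class = "titv_test")
}

#' Bootstrap test for transition enrichment or omission
#'
#' Resampling version of the transition-count test: each of `n_resamples`
#' resamples redraws the `n_total` substitution classifications independently,
#' each a transition with probability `p_transition` (default 1/3), and the
#' tail probability is estimated with the add-one rule
#' `p = (1 + #{resamples at least as extreme}) / (n_resamples + 1)`, so the
#' returned p-value is never 0. The tail must be chosen explicitly: `"lower"`
#' asks whether transitions are under-represented (omission), `"upper"`
#' whether they are enriched; `"two_sided"` doubles the smaller tail (capped
#' at 1). [titv_exact()] computes the same tail in closed form and is the
#' preferred choice when no resampling trace is needed.
#'
#' @param n_obs observed number of transitions.
#' @param n_total number of classified point substitutions (indels and
#'   unknowns excluded, see [count_transitions()]).
#' @param p_transition null transition probability (default `1/3`).
#' @param tail `"lower"`, `"upper"` or `"two_sided"`.
#' @param n_resamples number of resamples (default `1e6`).
#' @param seed RNG seed, recorded in the result.
#' @return object of class `titv_test` with the observed count, tail,
#'   `p_value`, `n_resamples`, `seed` and `mode`.
#' @examples
#' titv_bootstrap(1, 21, tail = "lower", n_resamples = 1e5, seed = 42)
#' @export
titv_bootstrap <- function(n_obs, n_total, p_transition = 1 / 3,
                           tail = c("lower", "upper", "two_sided"),
                           n_resamples = 1e6, seed = 1L) {
  tail <- .titv_validate(n_obs, n_total, p_transition, tail)
  stopifnot(n_resamples >= 1L)
  draws <- with_seed(seed, stats::rbinom(n_resamples, n_total, p_transition))
  p_low <- (1 + sum(draws <= n_obs)) / (n_resamples + 1)
  p_up  <- (1 + sum(draws >= n_obs)) / (n_resamples + 1)
  p <- switch(tail,
              lower = p_low,
              upper = p_up,
              two_sided = min(1, 2 * min(p_low, p_up)))
  .titv_result(n_obs, n_total, tail, p, n_resamples, seed, "bootstrap",
               p_transition)
}

#' Exact binomial tail for the transition-count test
#'
#' Closed form of the quantity [titv_bootstrap()] estimates: under the null
#' the transition count is Binomial(`n_total`, `p_transition`), so the lower
#' tail is `sum_{k <= n_obs} C(n_total, k) p^k (1-p)^(n_total-k)` and the
#' upper tail its `>=` counterpart.
#'
#' @inheritParams titv_bootstrap
#' @return object of class `titv_test` (`n_resamples = 0`, `mode = "exact"`).
#' @examples
#' titv_exact(1, 21, tail = "lower")  # p = 0.002306
#' @export
titv_exact <- function(n_obs, n_total, p_transition = 1 / 3,
                       tail = c("lower", "upper", "two_sided")) {
  tail <- .titv_validate(n_obs, n_total, p_transition, tail)
  p_low <- stats::pbinom(n_obs, n_total, p_transition)
  p_up  <- stats::pbinom(n_obs - 1, n_total, p_transition, lower.tail = FALSE)
  p <- switch(tail,
              lower = p_low,
              upper = p_up,
              two_sided = min(1, 2 * min(p_low, p_up)))
  .titv_result(n_obs, n_total, tail, p, 0L, NULL, "exact", p_transition)
}

#' @export
print.titv_test <- function(x, ...) {
  cat("<titv_test> ", x$n_transitions_observed, "/", x$n_total,
      " transitions, null p = ", format(x$p_transition, digits = 4),
      ", ", x$tail, " tail\n  p-value = ", format(x$p_value, digits = 4),
      if (x$mode == "bootstrap") {
        sprintf(" (bootstrap, %d resamples, seed %d)", x$n_resamples, x$seed)
      } else " (exact binomial)",
      "\n", sep = "")
  invisible(x)
}
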