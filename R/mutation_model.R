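# Mutation-label parsing and transition/transversion classification.

PURINES     <- c("A", "G")
PYRIMIDINES <- c("C", "T")

# Dash variants seen in printed mutation tables: hyphen-minus, en dash,
# em dash, minus sign, figure dash.
.DASHES <- c("‐", "‑", "‒", "–", "—", "−")

#' Normalize a mutation label to plain ASCII
#'
#' Printed mutation tables mix typographic conventions: deletions appear with
#' a Greek capital delta (`Δ410–421`), ranges use en or em dashes,
#' and whitespace varies. Normalization maps every delta variant to the token
#' `del` and every dash variant to `-`, trims whitespace, and leaves all other
#' characters untouched, so parsing is insensitive to the source typography.
#'
#' @param label character vector of raw mutation labels.
#' @return character vector of the same length in canonical ASCII form.
#' @examples
#' normalize_label("Δ410–421")  # "del410-421"
#' @export
normalize_label <- function(label) {
  stopifnot(is.character(label))
  x <- trimws(label)
  x <- gsub("Δ|δ", "del", x)        # Greek capital/small delta
  x <- gsub("^[Dd][Ee][Ll]\\.?:?\\s*", "del", x)
  for (d in .DASHES) x <- gsub(d, "-", x, fixed = TRUE)
  x
}

#' Parse a mutation label
#'
#' Recognizes two label dialects used for bacterial coding-sequence mutations:
#'
#' * substitutions `<REF><POS><ALT>`, e.g. `"A289C"` — reference base,
#'   1-based position within the gene's coding sequence, alternate base;
#' * deletions `del<START>-<END>` (any delta/dash variant, or a bare
#'   `<START>-<END>` range), e.g. `"Δ410–421"` — 1-based inclusive span.
#'
#' Anything else parses to `kind = "unknown"` without raising, so unparseable
#' labels flow through a pipeline as an explicit category rather than an
#' error. Positions are only checked for positivity: coding-sequence length
#' is not modelled, so no upper bound is enforced.
#'
#' @param label a single character string (see [normalize_label()] for the
#'   accepted typography).
#' @param strict if `TRUE`, an unparseable label raises an error instead of
#'   returning `kind = "unknown"`.
#' @return an object of class `parsed_mutation`: a list with `kind`
#'   (`"substitution"`, `"deletion"` or `"unknown"`), `ref_base`, `position`,
#'   `alt_base` (substitutions), `span_start`, `span_end` (deletions), and
#'   `raw` (the input label).
#' @examples
#' parse_mutation_label("A289C")
#' parse_mutation_label("Δ410–421")
#' parse_mutation_label("not-a-mutation")$kind
#' @seealso [classify_mutation()], [format.parsed_mutation()]
#' @export
parse_mutation_label <- function(label, strict = FALSE) {
  stopifnot(is.character(label), length(label) == 1L, !is.na(label),
            nzchar(trimws(label)))
  x <- normalize_label(label)
  out <- list(kind = "unknown", ref_base = NA_character_,
              position = NA_integer_, alt_base = NA_character_,
              span_start = NA_integer_, span_end = NA_integer_,
              raw = label)

  if (grepl("^[ACGTacgt][0-9]+[ACGTacgt]$", x)) {
    ref <- toupper(substr(x, 1L, 1L))
    alt <- toupper(substr(x, nchar(x), nchar(x)))
    pos <- as.integer(substr(x, 2L, nchar(x) - 1L))
    if (ref != alt && pos >= 1L) {
      out$kind <- "substitution"
      out$ref_base <- ref
      out$position <- pos
      out$alt_base <- alt
    }
  } else if (grepl("^(del)?[0-9]+-[0-9]+$", x)) {
    nums <- as.integer(strsplit(sub("^del", "", x), "-", fixed = TRUE)[[1L]])
    if (nums[1L] <= nums[2L] && nums[1L] >= 1L) {
      out$kind <- "deletion"
      out$span_start <- nums[1L]
      out$span_end <- nums[2L]
    }
  }

  if (strict && out$kind == "unknown") {
    stop("unparseable mutation label: ", sQuote(label), call. = FALSE)
  }
  structure(out, class = "parsed_mutation")
}

#' @describeIn parse_mutation_label canonical serialization:
#'   `"<REF><POS><ALT>"` for substitutions, `"del:<start>-<end>"` for
#'   deletions, the raw text for unknown labels. Parsing a canonical
#'   substitution or deletion label and re-serializing it is the identity.
#' @param x a `parsed_mutation`.
#' @param ... unused.
#' @export
format.parsed_mutation <- function(x, ...) {
  switch(x$kind,
    substitution = paste0(x$ref_base, x$position, x$alt_base),
    deletion     = sprintf("del:%d-%d", x$span_start, x$span_end),
    x$raw
  )
}

#' @export
print.parsed_mutation <- function(x, ...) {
  cat("<parsed_mutation> ", format(x), " [", x$kind, "]\n", sep = "")
  invisible(x)
}

#' Classify a mutation as transition, transversion or indel
#'
#' A substitution is a transition when both bases are purines (A, G) or both
#' pyrimidines (C, T), and a transversion otherwise; of the 12 ordered base
#' substitutions, 4 are transitions and 8 transversions, which is the origin
#' of the 1/3 transition null used by [titv_exact()]. Classification is
#' invariant under complementing both bases, so strand orientation does not
#' matter. Deletions classify as `"indel"`, unparseable labels as
#' `"unknown"`.
#'
#' @param x a `parsed_mutation` from [parse_mutation_label()], or a character
#'   vector of raw labels (parsed internally, vectorized).
#' @return character: `"transition"`, `"transversion"`, `"indel"` or
#'   `"unknown"` (vector when `x` is a character vector).
#' @examples
#' classify_mutation("A289C")  # transversion
#' classify_mutation("T326C")  # transition
#' classify_mutation("Δ410–421")  # indel
#' @export
classify_mutation <- function(x) {
  if (is.character(x)) {
    return(vapply(x, function(l) classify_mutation(parse_mutation_label(l)),
                  character(1L), USE.NAMES = FALSE))
  }
  stopifnot(inherits(x, "parsed_mutation"))
  switch(x$kind,
    deletion = "indel",
    unknown  = "unknown",
    substitution = {
      both_pur <- x$ref_base %in% PURINES     && x$alt_base %in% PURINES
      both_pyr <- x$ref_base %in% PYRIMIDINES && x$alt_base %in% PYRIMIDINES
      if (both_pur || both_pyr) "transition" else "transversion"
    }
  )
}

#' Count transitions among classified substitutions
#'
#' Tallies transitions over the identified point substitutions in a set of
#' mutation records. Indels, unparseable labels and unidentified lines are
#' excluded from both counts: the transition/transversion dichotomy (and the
#' 1/3 null it feeds) applies only to point substitutions.
#'
#' @param records a mutation-record data frame (see [read_mutation_table()]
#'   for the column contract); only `mutation` and `identified` are used.
#' @return list with `n_transitions` and `n_classified` (number of
#'   substitutions considered); `n_transitions <= n_classified` always.
#' @examples
#' fx <- study_fixtures()
#' count_transitions(fx$records$mutS)   # 8 of 15
#' @export
count_transitions <- function(records) {
  records <- validate_records(records)
  keep <- records$identified
  labs <- records$mutation[keep & nzchar(records$mutation)]
  if (length(labs) == 0L) {
    return(list(n_transitions = 0L, n_classified = 0L))
  }
  cls <- classify_mutation(labs)
  subst <- cls %in% c("transition", "transversion")
  list(n_transitions = sum(cls == "transition"),
       n_classified  = sum(subst))
}
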