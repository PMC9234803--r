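# Mutation-record tables: the per-line outcome format shared by all stages.
#
# One row per replicate line:
#   line_id    unique line identifier
#   strain     condition / strain background the line belongs to
#   evolved    logical: did the line evolve motility within the horizon?
#   day        day of emergence (numeric; NA when not evolved or not recorded)
#   gene       mutated gene ("unidentified" when the mutation was not located;
#              "" for censored lines)
#   mutation   mutation label as printed, e.g. "A289C", "Δ410–421"
#   identified logical: was the adaptive mutation located?

RECORD_COLUMNS <- c("line_id", "strain", "evolved", "day",
                    "gene", "mutation", "identified")

#' Assemble a mutation-record table
#'
#' Thin constructor that recycles scalar arguments, orders the columns and
#' validates the result. Censored lines (`evolved = FALSE`) carry `NA` days
#' and empty gene/mutation fields.
#'
#' @param line_id,strain,evolved,day,gene,mutation,identified column vectors
#'   (scalars are recycled to the longest length).
#' @return a validated `data.frame` of mutation records.
#' @export
mutation_records <- function(line_id, strain, evolved = TRUE, day = NA_real_,
                             gene = "", mutation = "", identified = TRUE) {
  df <- data.frame(line_id = as.character(line_id),
                   strain = as.character(strain),
                   evolved = as.logical(evolved),
                   day = as.numeric(day),
                   gene = as.character(gene),
                   mutation = as.character(mutation),
                   identified = as.logical(identified),
                   stringsAsFactors = FALSE)
  validate_records(df)
}

#' @keywords internal
validate_records <- function(records) {
  if (!is.data.frame(records)) {
    stop("mutation records must be a data.frame", call. = FALSE)
  }
  missing_cols <- setdiff(RECORD_COLUMNS, names(records))
  if (length(missing_cols) > 0L) {
    stop("mutation-record table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[RECORD_COLUMNS]
  records$evolved <- as.logical(records$evolved)
  records$identified <- as.logical(records$identified)
  records$day <- as.numeric(records$day)
  bad_day <- !is.na(records$day) & records$day <= 0
  if (any(bad_day)) {
    stop("non-positive emergence day at row(s): ",
         paste(which(bad_day), collapse = ", "), call. = FALSE)
  }
  rownames(records) <- NULL
  records
}

#' Read or write a mutation table in the standard CSV dialect
#'
#' The dialect is a UTF-8 CSV with header
#' `line_id,strain,evolved,day,gene,mutation,identified`; `evolved` and
#' `identified` are `TRUE`/`FALSE`, and `day` is left empty for lines that
#' never evolved. Malformed files raise an error naming the offending
#' column or row.
#'
#' @param path file path.
#' @return `read_mutation_table()` returns a validated record `data.frame`;
#'   `write_mutation_table()` returns `path` invisibly.
#' @examples
#' path <- system.file("extdata", "ar2_mutations.csv", package = "hotspotr")
#' head(read_mutation_table(path))
#' @export
read_mutation_table <- function(path) {
  header <- names(utils::read.csv(path, nrows = 1L, fileEncoding = "UTF-8"))
  char_cols <- intersect(c("line_id", "strain", "gene", "mutation"), header)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = stats::setNames(
                          rep("character", length(char_cols)), char_cols),
                        fileEncoding = "UTF-8")
  tryCatch(validate_records(df),
           error = function(e) stop("in ", path, ": ", conditionMessage(e),
                                    call. = FALSE))
}

#' @rdname read_mutation_table
#' @param records a mutation-record data frame.
#' @export
write_mutation_table <- function(records, path) {
  records <- validate_records(records)
  utils::write.csv(records, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

# Evaluate an expression with a private, restored RNG stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Render a proportion as a percentage string
#'
#' @param x proportion in `[0, 1]`.
#' @param digits decimal places (1 for spectrum fractions, 2 for evolved
#'   percentages).
#' @return character, e.g. `"95.2%"`.
#' @export
render_percent <- function(x, digits = 1L) {
  sprintf(paste0("%.", digits, "f%%"), 100 * x)
}
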