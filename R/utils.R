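#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## require named columns in a data frame, with the caller's table name in the
## message so schema errors point at the offending file
check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

check_nonneg <- function(x, what) {
  if (anyNA(x)) {
    stop(sprintf("%s: missing values are not allowed", what), call. = FALSE)
  }
  if (any(x < 0)) {
    stop(sprintf("%s: negative values are not allowed (rows %s)", what,
                 paste(utils::head(which(x < 0), 5L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

#' Read a CSV table with code columns kept as character
#'
#' Thin wrapper over [utils::read.csv()] used for every tabular input so that
#' food/commodity codes are never coerced to numbers.
#'
#' @param path file path.
#' @param required character vector of column names that must be present.
#' @param what label used in error messages (defaults to the file name).
#' @return a `data.frame`.
#' @keywords internal
read_table_csv <- function(path, required = character(), what = basename(path)) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, check.names = FALSE)
  codes <- intersect(names(df),
                     c("study_id", "commodity_code", "food_code", "person_id",
                       "target_commodity_code", "source", "group", "stratum",
                       "psu", "kind", "provenance", "code"))
  for (cc in codes) df[[cc]] <- as.character(df[[cc]])
  check_columns(df, required, what)
  df
}

write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
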