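#' Read a municipality table from CSV
#'
#' Reads a UTF-8, header-first CSV whose columns follow the canonical
#' municipality schema (see [validate_municipalities()]). Counts are parsed
#' as numbers; empty cells become `NA` and are later routed to the
#' inconsistent/incomplete exclusion by [apply_exclusions()]. Records that
#' violate a structural invariant (e.g. more equipped units than units)
#' raise an error naming the offending rows rather than being silently
#' dropped.
#'
#' @param path CSV file path.
#' @param strict error on invariant violations (default) instead of
#'   returning the table with a `violations` attribute.
#' @return A tibble of municipality records, ordered as on file.
#' @export
read_municipalities <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  spec <- readr::cols(
    id = readr::col_character(),
    region = readr::col_character(),
    pmaq_participant = readr::col_logical(),
    .default = readr::col_double())
  # readr's parsing-issue warning is superseded by the error raised below
  tbl <- suppressWarnings(
    readr::read_csv(path, col_types = spec, na = c("", "NA"),
                    progress = FALSE))
  missing_cols <- setdiff(municipality_columns(), names(tbl))
  if (length(missing_cols)) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  prob <- readr::problems(tbl)
  if (nrow(prob)) {
    stop("non-numeric or malformed value(s) at row(s) ",
         paste(unique(prob$row), collapse = ", "), call. = FALSE)
  }
  tbl <- tbl[, municipality_columns()]
  viol <- validate_municipalities(tbl)
  if (nrow(viol)) {
    if (strict) {
      stop("invalid record(s): ",
           paste(sprintf("row %d (%s): %s", viol$row, viol$id, viol$problem),
                 collapse = "; "), call. = FALSE)
    }
    attr(tbl, "violations") <- viol
  }
  tbl
}

#' Write a municipality table to CSV
#'
#' Canonical column order, UTF-8, decimal point, empty cell for `NA`.
#'
#' @param table municipality tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_municipalities <- function(table, path) {
  missing_cols <- setdiff(municipality_columns(), names(table))
  if (length(missing_cols)) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(table[, municipality_columns()], path, na = "",
                   progress = FALSE)
  invisible(path)
}
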