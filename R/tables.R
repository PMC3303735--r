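## Delimited-table I/O shared by every store: UTF-8, tab-separated, header row,
## RFC-4180-style double-quoting.  All columns round-trip as character; typed
## columns are re-cast on read from per-table schemas.

#' Write a data frame as a tab-separated table file
#'
#' @param df data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
dw_write_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = TRUE, qmethod = "double",
              row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-separated table file
#'
#' @param path input file path.
#' @param numeric_cols,integer_cols,logical_cols column names to re-cast;
#'   empty cells become `NA`.
#' @return data frame with character columns except where re-cast.
#' @export
dw_read_table <- function(path, numeric_cols = character(),
                          integer_cols = character(),
                          logical_cols = character()) {
  if (!file.exists(path))
    dw_stop("dw_parse_error", sprintf("table file not found: %s", path))
  df <- read.delim(path, sep = "\t", quote = "\"", colClasses = "character",
                   na.strings = NULL, check.names = FALSE,
                   fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  blank_na <- function(x) ifelse(x == "", NA_character_, x)
  for (cn in numeric_cols) if (cn %in% names(df))
    df[[cn]] <- as.numeric(blank_na(df[[cn]]))
  for (cn in integer_cols) if (cn %in% names(df))
    df[[cn]] <- as.integer(blank_na(df[[cn]]))
  for (cn in logical_cols) if (cn %in% names(df))
    df[[cn]] <- as.logical(blank_na(df[[cn]]))
  df
}

## ISO-8601 date helpers; dates travel as "YYYY-MM-DD" strings everywhere.
as_iso_date <- function(x) format(as.Date(x), "%Y-%m-%d")

is_iso_date <- function(x) {
  !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x) &
    !is.na(suppressWarnings(as.Date(x, format = "%Y-%m-%d")))
}

date_le <- function(a, b) as.Date(a) <= as.Date(b)

empty_df <- function(spec) {
  cols <- lapply(spec, function(type) {
    switch(type,
           character = character(0),
           numeric   = numeric(0),
           integer   = integer(0),
           logical   = logical(0))
  })
  as.data.frame(cols, stringsAsFactors = FALSE)
}
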