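#' Read a manual frailty index (MFI) table
#'
#' The manual FI scores each of 29 clinical items 0 (no deficit),
#' 0.5 (mild) or 1 (severe); the overall MFI is the mean of the 29 item
#' scores. The file must contain `mouse_id` and `date` columns; every
#' remaining column is treated as one item.
#'
#' @param path CSV path.
#' @param n_items Required number of item columns (default 29).
#' @return Data frame with `mouse_id`, `date` (`Date`), the item columns,
#'   and a computed `overall` column.
#' @export
read_mfi_table <- function(path, n_items = 29) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_mfi(df, n_items = n_items)
}

#' Validate an in-memory MFI table and compute overall scores
#'
#' @param df Data frame with `mouse_id`, `date` and item columns.
#' @param n_items Required number of item columns (default 29).
#' @return The validated data frame with `date` as `Date` and an
#'   `overall` column (mean of items).
#' @export
validate_mfi <- function(df, n_items = 29) {
  need <- c("mouse_id", "date")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("MFI table missing column(s): ", paste(miss, collapse = ", "))
  }
  item_cols <- setdiff(names(df), c(need, "overall"))
  if (length(item_cols) != n_items) {
    stop("MFI table must have exactly ", n_items, " item columns, found ",
         length(item_cols))
  }
  items <- as.matrix(df[, item_cols, drop = FALSE])
  if (!is.numeric(items)) stop("MFI item columns must be numeric")
  ok <- items %in% c(0, 0.5, 1)
  if (!all(ok)) {
    bad <- which(!matrix(ok, nrow(items)))[1]
    row <- (bad - 1) %% nrow(items) + 1
    col <- (bad - 1) %/% nrow(items) + 1
    stop("row ", row, ", item '", item_cols[col], "': value ",
         items[row, col], " not in {0, 0.5, 1}")
  }
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("unparseable MFI assay date")
  df$overall <- rowMeans(items)
  df
}
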