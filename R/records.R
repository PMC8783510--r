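# CSV serialization of chalkiness records.

RECORD_COLUMNS <- c("grain_id", "label", "chalky_score",
                    "chalk_area_percent", "layer", "threshold")

#' Write / read chalkiness records
#'
#' Deterministic column order, UTF-8, header always present; floating point
#' columns are serialized with 6 significant digits, so a read inverts a
#' write to within 1e-6 on values of magnitude 1.
#'
#' @param records data.frame with columns `grain_id`, `label`,
#'   `chalky_score`, `chalk_area_percent`, `layer`, `threshold`; extra
#'   columns (e.g. grouping keys) are preserved after the standard ones.
#' @param path CSV file path.
#' @return `read_records` returns the data.frame.
#' @export
write_records <- function(records, path) {
  assert_that(is.data.frame(records), "records must be a data.frame")
  missing_cols <- setdiff(RECORD_COLUMNS, names(records))
  assert_that(length(missing_cols) == 0,
              sprintf("records missing column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  extra <- setdiff(names(records), RECORD_COLUMNS)
  out <- records[, c(RECORD_COLUMNS, extra), drop = FALSE]
  for (nm in names(out))
    if (is.numeric(out[[nm]]) && !all(out[[nm]] == round(out[[nm]])))
      out[[nm]] <- signif(out[[nm]], 6)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: '%s'", path),
              class = "chalkcam_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing_cols <- setdiff(RECORD_COLUMNS, names(df))
  assert_that(length(missing_cols) == 0,
              sprintf("record file missing column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  df
}
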