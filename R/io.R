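# Tabular I/O for the pipeline's CSV interchange formats.

#' Write monitoring records to CSV
#'
#' Schema: `pwsid,contaminant_id,sample_date,value,unit,nondetect` with
#' ISO-8601 dates, `nondetect` in {0,1} and an empty `value` field for
#' non-detects.
#'
#' @param tests Tibble of monitoring records.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tests_csv <- function(tests, path) {
  out <- tests
  out$nondetect <- as.integer(out$nondetect)
  out$sample_date <- format(out$sample_date, "%Y-%m-%d")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read monitoring records from CSV
#'
#' @param path Path to a CSV in the [write_tests_csv()] schema.
#' @return A tibble with typed columns (`sample_date` as Date, `nondetect`
#'   logical, `value` numeric with NA for non-detects).
#' @export
read_tests_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    pwsid = readr::col_character(),
    contaminant_id = readr::col_character(),
    sample_date = readr::col_date(format = "%Y-%m-%d"),
    value = readr::col_double(),
    unit = readr::col_character(),
    nondetect = readr::col_integer()
  ))
  df$nondetect <- df$nondetect == 1L
  validate_test_records(df)
  df
}

validate_test_records <- function(records) {
  need <- c("pwsid", "contaminant_id", "sample_date", "value", "unit", "nondetect")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) {
    stop("monitoring records missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_xor <- is.na(records$value) != records$nondetect
  if (any(bad_xor)) {
    stop("records must have a value XOR be flagged non-detect (rows ",
         paste(utils::head(which(bad_xor), 5), collapse = ", "), ")",
         call. = FALSE)
  }
  neg <- !is.na(records$value) & records$value < 0
  if (any(neg)) {
    stop("negative concentration values (rows ",
         paste(utils::head(which(neg), 5), collapse = ", "), ")", call. = FALSE)
  }
  unknown <- setdiff(unique(records$unit), names(unit_registry()))
  if (length(unknown) > 0) {
    stop("unknown concentration units: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  invisible(records)
}
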