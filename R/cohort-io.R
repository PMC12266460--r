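#' Write / read a cohort CSV
#'
#' The on-disk format is RFC-4180 CSV with the columns in [cohort_columns],
#' UTF-8, missing values encoded as empty fields. `read_cohort()` validates
#' on read and the round trip `read_cohort(write_cohort(x))` is lossless up
#' to numeric printing precision.
#'
#' @param cohort A cohort tibble (see [simulate_cohort()]).
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a validated cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols) > 0) {
    rlang::abort(paste("cohort is missing columns:",
                       paste(missing_cols, collapse = ", ")))
  }
  readr::write_csv(cohort[, cohort_columns], path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("cohort file not found: %s", path))
  }
  cohort <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      arm = readr::col_character(),
      sex = readr::col_character(),
      .default = readr::col_double()
    ),
    na = c("", "NA"), progress = FALSE
  )
  validate_cohort(cohort)
}

#' Validate a cohort table
#'
#' Enforces the record invariants: all columns present; baseline weight
#' present and positive; all weights positive when present; survey scores in
#' \[0, 100\] when present; costs non-negative when present; arm and sex from
#' their respective label sets. Violations raise an error naming the first
#' offending row and column.
#'
#' @param cohort A cohort data frame.
#' @return The cohort as a tibble, columns ordered as [cohort_columns].
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols) > 0) {
    rlang::abort(paste("cohort is missing columns:",
                       paste(missing_cols, collapse = ", ")))
  }
  fail <- function(col, rows, why) {
    rlang::abort(sprintf("invalid cohort: column '%s', row %d: %s",
                         col, rows[1], why))
  }
  bad <- which(is.na(cohort$weight_m0) | cohort$weight_m0 <= 0)
  if (length(bad) > 0) fail("weight_m0", bad, "baseline weight must be present and > 0")
  for (col in c("weight_m4", "weight_m16", "weight_m22")) {
    bad <- which(!is.na(cohort[[col]]) & cohort[[col]] <= 0)
    if (length(bad) > 0) fail(col, bad, "weights must be > 0")
  }
  for (col in grep("^(htvas|sf36)_", cohort_columns, value = TRUE)) {
    x <- cohort[[col]]
    bad <- which(!is.na(x) & (x < 0 | x > 100))
    if (length(bad) > 0) fail(col, bad, "scores must lie in [0, 100]")
  }
  for (col in c("rx_cost_monthly", "other_cost_monthly")) {
    bad <- which(!is.na(cohort[[col]]) & cohort[[col]] < 0)
    if (length(bad) > 0) fail(col, bad, "costs must be non-negative")
  }
  bad <- which(!cohort$arm %in% c("education_control", "individual_coaching"))
  if (length(bad) > 0) {
    fail("arm", bad, "arm must be education_control or individual_coaching")
  }
  bad <- which(!cohort$sex %in% c("female", "male"))
  if (length(bad) > 0) fail("sex", bad, "sex must be female or male")
  tibble::as_tibble(cohort)[, cohort_columns]
}
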