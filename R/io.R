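# Cohort CSV schema I/O with strict validation.

#' Read a patient-level cohort CSV
#'
#' Strict reader for the cohort schema (`id`, `arm`, `gender`, the 14
#' continuous covariates, raw scores, LOS, cost). Unknown columns are
#' preserved but ignored downstream. Validation errors are exhaustive and
#' name the offending row and column: missing columns, non-numeric cells,
#' duplicate ids, and invalid `arm`/`gender` codes all abort.
#'
#' @param path CSV file path (UTF-8, '.' decimal point).
#' @return Cohort tibble in schema order.
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(cohort_schema(), names(raw))
  if (length(missing) > 0) {
    abort(paste0("Missing column(s): ", paste(missing, collapse = ", ")))
  }
  errors <- character(0)
  numeric_cols <- setdiff(cohort_schema(), c("id", "arm", "gender"))
  out <- raw
  for (col in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]))
    bad <- c(bad, which(is.na(raw[[col]])))
    if (length(bad) > 0) {
      errors <- c(errors, paste0(
        "column '", col, "', row(s) ",
        paste(head(sort(unique(bad)), 5), collapse = ", "),
        ": not a finite number"
      ))
    }
    out[[col]] <- parsed
  }
  dup <- unique(raw$id[duplicated(raw$id)])
  if (length(dup) > 0) {
    errors <- c(errors, paste0("duplicate id(s): ",
                               paste(head(dup, 5), collapse = ", ")))
  }
  bad_arm <- which(!raw$arm %in% c("SAT", "CAV"))
  if (length(bad_arm) > 0) {
    errors <- c(errors, paste0("column 'arm', row(s) ",
                               paste(head(bad_arm, 5), collapse = ", "),
                               ": must be SAT or CAV"))
  }
  bad_gender <- which(!raw$gender %in% c("F", "M"))
  if (length(bad_gender) > 0) {
    errors <- c(errors, paste0("column 'gender', row(s) ",
                               paste(head(bad_gender, 5), collapse = ", "),
                               ": must be F or M"))
  }
  if (length(errors) > 0) {
    abort(paste0("Cohort validation failed:\n  - ",
                 paste(errors, collapse = "\n  - ")))
  }
  out[, c(cohort_schema(), setdiff(names(out), cohort_schema()))]
}

#' Write a cohort in the canonical CSV schema
#'
#' Writes exactly the schema columns (derived columns such as potential
#' outcomes and metrics are dropped), so a fixed cohort serializes
#' byte-identically.
#'
#' @param data Cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  assert_cohort_columns(data, cohort_schema())
  readr::write_csv(data[, cohort_schema()], path, progress = FALSE)
  invisible(path)
}

#' Write ground-truth effects as JSON
#'
#' @param gt A [ground_truth()] object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "dvt_ground_truth"))
  jsonlite::write_json(
    list(
      true_effect = setNames(as.list(gt$effects$effect), gt$effects$metric),
      mc_se = setNames(as.list(gt$effects$se), gt$effects$metric),
      n_mc = gt$n_mc,
      n_used = gt$n_used,
      exclusion_rate = gt$exclusion_rate
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
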