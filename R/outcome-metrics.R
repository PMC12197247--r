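# The six outcome metrics derived from raw admission fields, and the
# exclusion rule for records whose symptom score did not change (the ratio
# metrics are undefined there).

# Vectorized metric arithmetic shared by compute_outcomes() and the
# ground-truth oracle. Returns a plain matrix with one column per metric.
outcome_metric_table <- function(day1, discharge, los, cost) {
  reduction <- day1 - discharge
  ipr <- reduction / day1 * 100
  dir <- ipr / los
  cer <- cost / reduction
  dic <- cost / dir
  cle <- cer / los
  cbind(ipr = ipr, dir = dir, cer = cer, dic = dic, cle = cle, los = los)
}

#' Compute the six outcome metrics for every record
#'
#' Appends `ipr`, `dir`, `cer`, `dic`, `cle` and `los` columns:
#' IPR = (Day-1 score - discharge score)/Day-1 score x 100 (percent),
#' DIR = IPR/LOS, CER = cost/absolute score reduction, DIC = cost/DIR,
#' CLE = CER/LOS, LOS = length of stay in days. Worsening (discharge above
#' Day-1) yields negative IPR and is retained. Records with a zero score
#' difference get `NA` ratio metrics and raise a warning: they carry an
#' exclusion signal and should be removed with [apply_exclusions()] first.
#'
#' @param data Cohort tibble with `score_day1`, `score_discharge`,
#'   `los_days`, `cost_cny` (and `id`).
#' @return `data` with the six metric columns appended.
#' @export
#' @examples
#' rec <- tibble::tibble(id = "a", score_day1 = 10, score_discharge = 0,
#'                       los_days = 5, cost_cny = 5000)
#' compute_outcomes(rec)[, c("ipr", "dir", "cer", "dic", "cle", "los")]
compute_outcomes <- function(data) {
  assert_cohort_columns(
    data, c("id", "score_day1", "score_discharge", "los_days", "cost_cny")
  )
  bad_day1 <- data$score_day1 <= 0
  bad_los <- data$los_days <= 0
  if (any(bad_day1) || any(bad_los)) {
    offenders <- unique(data$id[bad_day1 | bad_los])
    abort(paste0(
      "Invalid record(s): Day-1 score and LOS must be positive for ",
      paste(head(offenders, 5), collapse = ", "),
      if (length(offenders) > 5) ", ..." else ""
    ))
  }
  m <- outcome_metric_table(data$score_day1, data$score_discharge,
                            data$los_days, data$cost_cny)
  zero <- data$score_day1 == data$score_discharge
  if (any(zero)) {
    m[zero, c("ipr", "dir", "cer", "dic", "cle")] <- NA_real_
    warn(paste0(
      sum(zero), " record(s) have a zero symptom-score difference; ",
      "their ratio metrics are undefined (NA). ",
      "Use apply_exclusions() to drop them."
    ))
  }
  out <- data
  for (nm in colnames(m)) out[[nm]] <- unname(m[, nm])
  out
}

#' Exclude records on which the outcome metrics are undefined
#'
#' Drops records whose Day-1 and discharge symptom scores are identical
#' (zero score difference: CER and DIC involve division by the reduction),
#' plus any record failing the validity preconditions (nonpositive Day-1
#' score or LOS). Negative improvement (worsening) is retained.
#'
#' @param data Cohort tibble.
#' @return List with `cohort` (the surviving records) and `log` (tibble of
#'   dropped `id` + `reason`).
#' @export
apply_exclusions <- function(data) {
  assert_cohort_columns(
    data, c("id", "score_day1", "score_discharge", "los_days")
  )
  if (nrow(data) == 0) abort("Cohort is empty.")
  reason <- rep(NA_character_, nrow(data))
  reason[data$score_day1 == data$score_discharge] <- "zero_score_difference"
  reason[data$score_day1 <= 0] <- "nonpositive_day1_score"
  reason[data$los_days <= 0] <- "nonpositive_los"
  dropped <- !is.na(reason)
  if (all(dropped)) {
    abort("All records excluded; no analyzable cohort remains.")
  }
  list(
    cohort = data[!dropped, , drop = FALSE],
    log = tibble::tibble(id = data$id[dropped], reason = reason[dropped])
  )
}
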