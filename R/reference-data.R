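# Published reference estimates shipped with the package.

#' Reference treatment-effect estimates and ensemble weights
#'
#' Per-method and ensemble-weighted treatment-effect estimates (ATE, ATT,
#' ATC and double-residual) for the six outcome metrics, as reported by a
#' published retrospective CAV-versus-SAT cohort analysis, together with
#' the composite ensemble weights that analysis assigned to the four
#' matching methods (nearest caliper 0.362, optimal exact 0.239, genetic
#' 0.219, Mahalanobis 0.180). `reference_effects()` returns the effect
#' table (rows with `method = "weighted"` are the published weighted
#' averages); `reference_weights()` the named weight vector. Useful as a
#' fixed input for exercising and checking the weighted-aggregation layer.
#'
#' @return A tibble (effects) or named numeric vector (weights).
#' @export
reference_effects <- function() {
  readr::read_csv(
    system.file("extdata", "reference_effects.csv", package = "dvtmatch",
                mustWork = TRUE),
    col_types = readr::cols(
      outcome = readr::col_character(),
      method = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
}

#' @rdname reference_effects
#' @export
reference_weights <- function() {
  c(nearest_caliper = 0.362, optimal_exact = 0.239, genetic = 0.219,
    mahalanobis = 0.180)
}
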