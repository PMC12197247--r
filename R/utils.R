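# Internal helpers shared across modules.

#' Names of the 17 baseline matching covariates
#'
#' Demographics (age, gender, height, weight), the Wells clinical probability
#' score, and twelve admission laboratory values (blood counts and
#' coagulation panel). These are the covariates entering the propensity
#' model, every matching algorithm, balance diagnostics, and all outcome
#' models.
#'
#' @return Character vector of column names in the cohort schema.
#' @export
dvt_covariates <- function() {
  c(
    "age", "gender", "height_cm", "weight_kg", "wells",
    "wbc", "rbc", "hgb", "plt", "hct", "pt", "inr",
    "aptt", "tt", "fib", "ddimer", "fdp"
  )
}

#' Names of the six outcome metrics
#'
#' IPR (improvement rate, percent), DIR (daily improvement rate,
#' percent/day), CER (cost-effectiveness ratio, CNY per score point), DIC
#' (daily improvement cost, CNY), CLE (cost-LOS efficiency, CNY per day) and
#' LOS (length of stay, days).
#'
#' @return Character vector of metric column names.
#' @export
dvt_outcomes <- function() {
  c("ipr", "dir", "cer", "dic", "cle", "los")
}

#' Hypothesis directions used for one-sided sensitivity tests
#'
#' Benefit of combined therapy is hypothesized as positive for IPR, DIR and
#' CLE, negative for DIC (costs fall), and two-sided for LOS and CER where
#' no direction is presumed.
#'
#' @return Named character vector over [dvt_outcomes()] with values
#'   `"greater"`, `"less"` or `"two.sided"`.
#' @export
dvt_outcome_directions <- function() {
  c(
    ipr = "greater", dir = "greater", cer = "two.sided",
    dic = "less", cle = "greater", los = "two.sided"
  )
}

# Cohort CSV schema: column order is contractual for write/read round-trips.
cohort_schema <- function() {
  c(
    "id", "arm", "gender", "age", "height_cm", "weight_kg", "wells",
    "wbc", "rbc", "hgb", "plt", "hct", "pt", "inr", "aptt", "tt",
    "fib", "ddimer", "fdp", "score_day1", "score_discharge",
    "los_days", "cost_cny"
  )
}

# Evaluate `code` under a temporary RNG state; global stream is untouched.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-record substream seed: a fixed hash of (seed, index) so
# that record i's draws do not depend on how many records precede it.
# Arithmetic kept below 2^53 so doubles are exact; result is in [1, 2^31-2].
record_seed <- function(seed, i) {
  s0 <- as.numeric(seed) %% 2147483647
  h <- (s0 * 48271 + 11) %% 2147483647
  as.integer((h + as.numeric(i) * 104729) %% 2147483646 + 1)
}

# Inverse-CDF sampler for a truncated normal; u in (0,1).
q_truncnorm <- function(u, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) {
    return(rep(mean, length(u)))
  }
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  p <- pl + u * (pu - pl)
  # Guard against qnorm(0/1) = +-Inf from extreme uniforms: truncate rather
  # than return a non-finite covariate.
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  qnorm(p, mean, sd)
}

# Coerce the gender column ("F"/"M") to a male indicator in {0,1}.
gender_indicator <- function(x) {
  if (is.numeric(x)) {
    stopifnot(all(x %in% c(0, 1)))
    return(as.numeric(x))
  }
  as.numeric(x == "M")
}

# Build the numeric covariate matrix used by matching and forests:
# continuous columns as-is, gender as 0/1 male indicator.
covariate_matrix <- function(data, covariates) {
  missing <- setdiff(covariates, names(data))
  if (length(missing) > 0) {
    abort(paste0(
      "Missing covariate column(s): ", paste(missing, collapse = ", ")
    ))
  }
  x <- as.data.frame(data[covariates])
  if ("gender" %in% covariates) {
    x$gender <- gender_indicator(x$gender)
  }
  m <- as.matrix(x)
  if (!all(is.finite(m))) {
    abort("Non-finite covariate values in cohort.")
  }
  storage.mode(m) <- "double"
  rownames(m) <- data$id
  m
}

# Column-standardize a covariate matrix (mean 0, sd 1); constant columns are
# left centered with unit divisor.
standardize_columns <- function(m) {
  mu <- colMeans(m)
  sigma <- apply(m, 2, sd)
  sigma[!is.finite(sigma) | sigma < 1e-12] <- 1
  sweep(sweep(m, 2, mu, "-"), 2, sigma, "/")
}

assert_cohort_columns <- function(data, cols) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(paste0(
      "Cohort is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}
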