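# Propensity model and covariate-balance diagnostics.

#' Fit the propensity (treatment-assignment) model
#'
#' Maximum-likelihood main-effects logistic regression of arm (CAV = 1) on
#' the baseline covariates, continuous covariates z-scored and gender coded
#' 0/1 (male). Constant covariates are dropped with a warning. Perfect or
#' quasi-perfect separation triggers a ridge-stabilized refit (small L2
#' penalty on the standardized slopes) with a warning, keeping every score
#' strictly inside (0, 1).
#'
#' @param data Cohort tibble with an `arm` column (`"SAT"`/`"CAV"`).
#' @param covariates Covariate names; default [dvt_covariates()].
#' @return Object of class `propensity_model`: coefficients on the
#'   standardized scale, per-record `scores` (probabilities) and
#'   `logit_scores`, plus the record ids and arms needed by the matchers.
#' @export
fit_propensity <- function(data, covariates = dvt_covariates()) {
  assert_cohort_columns(data, c("id", "arm"))
  arms <- data$arm
  if (length(unique(arms)) < 2) {
    abort("Both arms must be present to fit a propensity model.")
  }
  x <- covariate_matrix(data, covariates)
  keep <- apply(x, 2, function(col) sd(col) > 1e-12)
  if (!all(keep)) {
    warn(paste0("Dropping constant covariate(s): ",
                paste(colnames(x)[!keep], collapse = ", ")))
    x <- x[, keep, drop = FALSE]
  }
  # Continuous covariates are z-scored; binary gender stays on the 0/1
  # scale so its coefficient is a log odds ratio.
  z <- x
  cont <- setdiff(colnames(x), "gender")
  if (length(cont) > 0) {
    z[, cont] <- standardize_columns(x[, cont, drop = FALSE])
  }
  y <- as.numeric(arms == "CAV")
  if (ncol(z) == 0) {
    p <- rep(mean(y), length(y))
    return(structure(
      list(
        coefficients = c(`(Intercept)` = qlogis(mean(y))),
        scores = setNames(p, data$id),
        logit_scores = setNames(rep(qlogis(mean(y)), length(y)), data$id),
        id = data$id, arm = arms, covariates = character(0), ridge = FALSE
      ),
      class = "propensity_model"
    ))
  }

  fit <- suppressWarnings(
    glm(y ~ z, family = binomial(), control = list(maxit = 100))
  )
  p <- fitted(fit)
  ridge <- FALSE
  if (!fit$converged || any(p < 1e-10 | p > 1 - 1e-10) ||
      any(!is.finite(coef(fit)))) {
    warn("Separation detected in the propensity fit; refitting with a small ridge penalty.")
    ridge <- TRUE
    beta <- ridge_logistic(cbind(1, z), y, lambda = 1e-2)
    eta <- drop(cbind(1, z) %*% beta)
    p <- plogis(eta)
    coefs <- setNames(beta, c("(Intercept)", colnames(z)))
  } else {
    coefs <- setNames(coef(fit), c("(Intercept)", colnames(z)))
    eta <- qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))
  }
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  structure(
    list(
      coefficients = coefs,
      scores = setNames(as.numeric(p), data$id),
      logit_scores = setNames(as.numeric(eta), data$id),
      id = data$id,
      arm = arms,
      covariates = colnames(z),
      ridge = ridge
    ),
    class = "propensity_model"
  )
}

# Penalized IRLS for logistic regression; penalty on slopes only. Used as a
# numerical stabilizer when the MLE diverges under separation.
ridge_logistic <- function(x, y, lambda = 1e-2, maxit = 200, tol = 1e-10) {
  p <- ncol(x)
  pen <- diag(c(0, rep(lambda, p - 1)))
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(x %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    zadj <- eta + (y - mu) / w
    xtw <- t(x * w)
    beta_new <- solve(xtw %*% x + pen, xtw %*% zadj)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  drop(beta)
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("Propensity model (logistic", if (x$ridge) ", ridge-stabilized" else "",
      "): ", length(x$id), " records, ", sum(x$arm == "CAV"),
      " treated\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @rdname fit_propensity
#' @param x A `propensity_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.propensity_model <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname fit_propensity
#' @exportS3Method generics::glance
#' @export
glance.propensity_model <- function(x, ...) {
  tibble::tibble(
    n = length(x$id),
    n_treated = sum(x$arm == "CAV"),
    ridge = x$ridge,
    score_min = min(x$scores),
    score_max = max(x$scores)
  )
}

#' Standardized mean difference between two groups
#'
#' Continuous: `|mean_t - mean_c| / sqrt((var_t + var_c)/2)` with sample
#' variances. Binary (values in 0/1):
#' `|p_t - p_c| / sqrt((p_t(1-p_t) + p_c(1-p_c))/2)`. A zero pooled spread
#' with equal means returns 0; with unequal means it returns `Inf` with a
#' warning.
#'
#' @param values_t,values_c Numeric vectors for the two groups.
#' @param kind `"continuous"` or `"binary"`.
#' @return A single nonnegative number (possibly `Inf`).
#' @export
smd <- function(values_t, values_c, kind = c("continuous", "binary")) {
  kind <- match.arg(kind)
  if (length(values_t) == 0 || length(values_c) == 0) {
    abort("Both groups must be nonempty.")
  }
  if (kind == "binary") {
    if (!all(c(values_t, values_c) %in% c(0, 1))) {
      abort("Binary SMD requires values in {0, 1}.")
    }
    pt_ <- mean(values_t)
    pc_ <- mean(values_c)
    num <- abs(pt_ - pc_)
    denom <- sqrt((pt_ * (1 - pt_) + pc_ * (1 - pc_)) / 2)
  } else {
    num <- abs(mean(values_t) - mean(values_c))
    vt <- if (length(values_t) > 1) var(values_t) else 0
    vc <- if (length(values_c) > 1) var(values_c) else 0
    denom <- sqrt((vt + vc) / 2)
  }
  if (denom < 1e-12) {
    if (num < 1e-12) {
      return(0)
    }
    warn("Zero pooled spread with unequal means; SMD is infinite.")
    return(Inf)
  }
  num / denom
}

# SMD for every covariate between the two arms of `data` (rows restricted
# to `ids_t` / `ids_c`).
smd_profile <- function(data, covariates, ids_t, ids_c) {
  x <- covariate_matrix(data, covariates)
  vapply(covariates, function(nm) {
    kind <- if (nm == "gender") "binary" else "continuous"
    smd(x[ids_t, nm], x[ids_c, nm], kind = kind)
  }, numeric(1))
}

#' Covariate balance before and after matching
#'
#' Absolute standardized mean differences for every matching covariate,
#' computed on the full cohort (before) and on the matched pairs (after),
#' with the mean and maximum across covariates as summary statistics.
#'
#' @param data Cohort tibble.
#' @param matched A [matched_dataset][match_nearest_caliper] object.
#' @param covariates Covariate names; default [dvt_covariates()].
#' @return A `balance_table` tibble (covariate, smd_before, smd_after) with
#'   `mean_smd`/`max_smd` attributes; see [glance.balance_table()].
#' @export
balance_report <- function(data, matched, covariates = dvt_covariates()) {
  pairs <- matched$pairs
  missing_ids <- setdiff(c(pairs$treated_id, pairs$control_id), data$id)
  if (length(missing_ids) > 0) {
    abort(paste0("Matched ids absent from cohort: ",
                 paste(head(missing_ids, 5), collapse = ", ")))
  }
  before <- smd_profile(data, covariates,
                        data$id[data$arm == "CAV"],
                        data$id[data$arm == "SAT"])
  after <- smd_profile(data, covariates, pairs$treated_id, pairs$control_id)
  out <- tibble::tibble(
    covariate = covariates,
    smd_before = unname(before),
    smd_after = unname(after)
  )
  structure(
    out,
    class = c("balance_table", class(out)),
    method = matched$method,
    mean_smd = mean(after),
    max_smd = max(after)
  )
}

#' @rdname balance_report
#' @param x A `balance_table`.
#' @param ... Unused.
#' @exportS3Method generics::glance
#' @export
glance.balance_table <- function(x, ...) {
  tibble::tibble(
    method = attr(x, "method") %||% NA_character_,
    mean_smd = attr(x, "mean_smd"),
    max_smd = attr(x, "max_smd")
  )
}
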