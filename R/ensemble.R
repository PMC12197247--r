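# Five-dimension quality scoring of matched datasets and the composite
# ensemble weights: covariate balance (mean and max SMD, weighted inversely),
# out-of-fold predictive R^2, Rosenbaum robustness at gamma = 1.5, and
# sample-size retention, combined as 25/15/25/30/5.

#' Cross-validated predictive R-squared on a matched sample
#'
#' For each outcome metric, fits a random-forest regression of the outcome
#' on the baseline covariates plus the arm indicator, with k-fold
#' cross-validation stratified by arm, and reports the out-of-fold
#' `R^2 = 1 - SSE/SST`. Negative values are retained (the forest can be
#' worse than the mean on held-out folds). A constant outcome yields 0 with
#' a warning.
#'
#' @param matched A `matched_dataset`.
#' @param data Cohort tibble with the outcome metric columns (see
#'   [compute_outcomes()]).
#' @param outcomes Metric names; default [dvt_outcomes()].
#' @param covariates Covariate names; default [dvt_covariates()].
#' @param k Number of folds (>= 2).
#' @param seed Integer seed (fold assignment and forests).
#' @param num_trees Trees per forest.
#' @return Tibble with columns `outcome`, `r2`.
#' @export
cv_r2 <- function(matched, data, outcomes = dvt_outcomes(),
                  covariates = dvt_covariates(), k = 5, seed = 1L,
                  num_trees = 500) {
  if (k < 2) abort("k must be >= 2.")
  ids <- matched_ids(matched)
  if (length(ids) < 2 * k) abort("Matched sample smaller than 2k records.")
  rows <- data[match(ids, data$id), , drop = FALSE]
  assert_cohort_columns(rows, c("arm", outcomes))
  x <- covariate_matrix(rows, covariates)
  df <- as.data.frame(x)
  df$arm <- as.numeric(rows$arm == "CAV")

  folds <- with_seed(record_seed(seed, 31L), {
    f <- integer(nrow(rows))
    for (a in unique(df$arm)) {
      idx <- which(df$arm == a)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  })

  r2 <- vapply(outcomes, function(oc) {
    y <- rows[[oc]]
    if (sd(y) < 1e-12) {
      warn(paste0("Outcome '", oc, "' is constant on the matched sample; ",
                  "R^2 reported as 0."))
      return(0)
    }
    pred <- numeric(length(y))
    for (fold in seq_len(k)) {
      hold <- folds == fold
      fit <- ranger::ranger(
        x = df[!hold, , drop = FALSE], y = y[!hold],
        num.trees = num_trees, seed = record_seed(seed, 100L + fold),
        num.threads = 1
      )
      pred[hold] <- predict(
        fit, data = df[hold, , drop = FALSE], num.threads = 1
      )$predictions
    }
    1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  }, numeric(1))

  tibble::tibble(outcome = outcomes, r2 = unname(r2))
}

#' Proportion of outcomes robust to hidden bias at a given gamma
#'
#' For each outcome metric, computes the Rosenbaum upper-bound p-value on
#' the matched-pair differences (one-sided in the outcome's hypothesized
#' benefit direction, two-sided for LOS and CER; see
#' [dvt_outcome_directions()]) and returns the fraction of outcomes whose
#' upper bound stays below `alpha`.
#'
#' @param matched A `matched_dataset`.
#' @param data Cohort tibble with outcome metric columns.
#' @param gamma Hidden-bias odds ratio (>= 1); default 1.5.
#' @param alpha Significance level.
#' @param outcomes Metric names.
#' @param directions Named direction vector over `outcomes`.
#' @return Proportion in [0, 1].
#' @export
rosenbaum_robustness <- function(matched, data, gamma = 1.5, alpha = 0.05,
                                 outcomes = dvt_outcomes(),
                                 directions = dvt_outcome_directions()) {
  if (gamma < 1) abort("gamma must be >= 1.")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1).")
  if (nrow(matched$pairs) < 5) abort("Need at least 5 matched pairs.")
  sig <- vapply(outcomes, function(oc) {
    d <- pair_differences(matched, data, oc)
    b <- directional_bounds(d, gamma, directions[[oc]])
    b$p_upper < alpha
  }, logical(1))
  mean(sig)
}

# Treated-minus-control outcome difference for each matched pair.
pair_differences <- function(matched, data, outcome) {
  assert_cohort_columns(data, c("id", outcome))
  v <- setNames(data[[outcome]], data$id)
  unname(v[matched$pairs$treated_id] - v[matched$pairs$control_id])
}

#' Assemble the five quality dimensions for each matched dataset
#'
#' Convenience wrapper producing one row per matching method: mean/max
#' post-match SMD, average cross-validated R^2 across outcomes, Rosenbaum
#' robustness at `gamma`, and treated-arm retention.
#'
#' @inheritParams cv_r2
#' @param matched_list Named list of `matched_dataset` objects.
#' @param gamma,alpha Passed to [rosenbaum_robustness()].
#' @return Tibble with columns `method`, `mean_smd`, `max_smd`, `cv_r2`,
#'   `robustness`, `retention`.
#' @export
method_quality <- function(matched_list, data,
                           covariates = dvt_covariates(),
                           outcomes = dvt_outcomes(), k = 5,
                           gamma = 1.5, alpha = 0.05, seed = 1L,
                           num_trees = 500) {
  purrr::map_dfr(matched_list, function(m) {
    bal <- balance_report(data, m, covariates)
    r2 <- cv_r2(m, data, outcomes, covariates, k = k, seed = seed,
                num_trees = num_trees)
    tibble::tibble(
      method = m$method,
      mean_smd = attr(bal, "mean_smd"),
      max_smd = attr(bal, "max_smd"),
      cv_r2 = mean(r2$r2),
      robustness = rosenbaum_robustness(m, data, gamma = gamma,
                                        alpha = alpha, outcomes = outcomes),
      retention = m$retained_n / m$n_treated_total
    )
  })
}

# Share-of-sum normalization; all-zero input degrades to equal shares.
share_of_sum <- function(x) {
  x <- pmax(x, 0)
  s <- sum(x)
  if (s < 1e-15) {
    return(rep(1 / length(x), length(x)))
  }
  x / s
}

#' Composite ensemble weights across matching methods
#'
#' Each quality dimension is converted to a per-method share in [0, 1]:
#' balance dimensions as normalized inverse SMD `1/(smd + eps)` (better
#' balance, larger share), average CV-R^2 floored at zero then normalized,
#' and robustness and retention normalized directly. The composite is the
#' dimension-weighted sum -- mean SMD 25%, max SMD 15%, predictive R^2 25%,
#' Rosenbaum robustness 30%, retention 5% -- renormalized to sum to one.
#'
#' @param qualities Tibble from [method_quality()] (columns `method`,
#'   `mean_smd`, `max_smd`, `cv_r2`, `robustness`, `retention`).
#' @param dim_weights Named dimension weights summing to 1.
#' @param eps Guard against division by zero in the inverse-SMD shares.
#' @return An `ensemble_weights` tibble (`method`, `weight`) with the
#'   per-dimension share matrix attached as attribute `"shares"`.
#' @export
composite_weight <- function(qualities,
                             dim_weights = c(mean_smd = 0.25, max_smd = 0.15,
                                             cv_r2 = 0.25, robustness = 0.30,
                                             retention = 0.05),
                             eps = 1e-6) {
  req <- c("method", "mean_smd", "max_smd", "cv_r2", "robustness", "retention")
  missing <- setdiff(req, names(qualities))
  if (length(missing) > 0) {
    abort(paste0("qualities is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (abs(sum(dim_weights) - 1) > 1e-8) {
    abort("dim_weights must sum to 1.")
  }
  if (any(qualities$robustness < 0 | qualities$robustness > 1)) {
    abort("robustness must lie in [0, 1].")
  }
  if (any(qualities$retention <= 0 | qualities$retention > 1)) {
    abort("retention must lie in (0, 1].")
  }
  n <- nrow(qualities)
  if (n < 1) abort("Need at least one method.")
  shares <- cbind(
    mean_smd = share_of_sum(1 / (qualities$mean_smd + eps)),
    max_smd = share_of_sum(1 / (qualities$max_smd + eps)),
    cv_r2 = share_of_sum(qualities$cv_r2),
    robustness = share_of_sum(qualities$robustness),
    retention = share_of_sum(qualities$retention)
  )
  rownames(shares) <- qualities$method
  composite <- drop(shares[, names(dim_weights), drop = FALSE] %*%
                      dim_weights)
  weights <- composite / sum(composite)
  out <- tibble::tibble(method = qualities$method, weight = unname(weights))
  structure(
    out,
    class = c("ensemble_weights", class(out)),
    shares = shares,
    dim_weights = dim_weights
  )
}

#' @rdname composite_weight
#' @param x An `ensemble_weights` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
#' @export
glance.ensemble_weights <- function(x, ...) {
  tibble::tibble(
    n_methods = nrow(x),
    top_method = x$method[which.max(x$weight)],
    top_weight = max(x$weight)
  )
}
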