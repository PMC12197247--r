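# T-learner counterfactual estimation on matched samples, the
# double-residual cross-check, impurity-based variable importance, and
# ensemble-weighted aggregation across matching methods.

# Rows entering an estimator: the matched sample, or the full cohort when
# matching was skipped (matched = NULL).
analysis_rows <- function(matched, data) {
  if (is.null(matched)) {
    return(data)
  }
  data[match(matched_ids(matched), data$id), , drop = FALSE]
}

#' T-learner counterfactual predictions and individual treatment effects
#'
#' Fits one random-forest regression of the outcome on the baseline
#' covariates per arm (treated-only and control-only models), predicts both
#' potential outcomes for every matched record, and returns the individual
#' treatment effect `ite = y1_hat - y0_hat`. Deterministic for a fixed
#' seed.
#'
#' @param matched A `matched_dataset`.
#' @param data Cohort tibble with the outcome column.
#' @param outcome Outcome metric name.
#' @param covariates Covariate names; default [dvt_covariates()].
#' @param seed Integer seed.
#' @param num_trees Trees per forest (default 500).
#' @return An `ite_vector` tibble: `id`, `arm`, `y1_hat`, `y0_hat`, `ite`.
#' @export
t_learner <- function(matched, data, outcome,
                      covariates = dvt_covariates(), seed = 1L,
                      num_trees = 500) {
  rows <- analysis_rows(matched, data)
  assert_cohort_columns(rows, c("id", "arm", outcome))
  n_t <- sum(rows$arm == "CAV")
  n_c <- sum(rows$arm == "SAT")
  if (n_t < 10) abort("Treated arm has fewer than 10 records.")
  if (n_c < 10) abort("Control arm has fewer than 10 records.")
  x <- as.data.frame(covariate_matrix(rows, covariates))
  y <- rows[[outcome]]
  is_t <- rows$arm == "CAV"

  fit_arm <- function(sel, salt) {
    ranger::ranger(
      x = x[sel, , drop = FALSE], y = y[sel], num.trees = num_trees,
      seed = record_seed(seed, salt), num.threads = 1,
      importance = "impurity"
    )
  }
  fit1 <- fit_arm(is_t, 1L)
  fit0 <- fit_arm(!is_t, 2L)
  y1 <- predict(fit1, data = x, num.threads = 1)$predictions
  y0 <- predict(fit0, data = x, num.threads = 1)$predictions

  out <- tibble::tibble(
    id = rows$id,
    arm = rows$arm,
    y1_hat = y1,
    y0_hat = y0,
    ite = y1 - y0
  )
  structure(
    out,
    class = c("ite_vector", class(out)),
    outcome = outcome,
    method = if (is.null(matched)) "unmatched" else matched$method,
    importance_treated = fit1$variable.importance,
    importance_control = fit0$variable.importance
  )
}

#' Average treatment effects from an ITE vector
#'
#' ATE is the mean individual effect over all matched records, ATT the mean
#' over treated records, ATC over controls, so the identity
#' `ate = (n_t * att + n_c * atc) / (n_t + n_c)` holds exactly.
#'
#' @param ite An `ite_vector` from [t_learner()].
#' @return One-row tibble with `ate`, `att`, `atc`.
#' @export
treatment_effects <- function(ite) {
  assert_cohort_columns(ite, c("arm", "ite"))
  is_t <- ite$arm == "CAV"
  if (!any(is_t) || all(is_t)) abort("Both arms must be present.")
  tibble::tibble(
    ate = mean(ite$ite),
    att = mean(ite$ite[is_t]),
    atc = mean(ite$ite[!is_t])
  )
}

#' @rdname treatment_effects
#' @param x An `ite_vector`.
#' @param ... Unused.
#' @exportS3Method generics::glance
#' @export
glance.ite_vector <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(outcome = attr(x, "outcome"),
                   method = attr(x, "method")),
    treatment_effects(x)
  )
}

#' Double-residual (residual-on-residual) treatment effect
#'
#' Both the outcome and the treatment indicator are regressed on the
#' baseline covariates with random forests, using out-of-fold predictions
#' (k folds stratified by arm); the effect is the least-squares slope of
#' the outcome residuals on the treatment residuals (through the origin by
#' default, since both residual vectors are centered up to fold noise).
#'
#' @inheritParams t_learner
#' @param k Number of folds.
#' @param intercept If `TRUE`, fit the residual regression with an
#'   intercept.
#' @return A single number.
#' @export
double_residual <- function(matched, data, outcome,
                            covariates = dvt_covariates(), k = 5,
                            seed = 1L, num_trees = 500,
                            intercept = FALSE) {
  rows <- analysis_rows(matched, data)
  assert_cohort_columns(rows, c("id", "arm", outcome))
  if (sum(rows$arm == "CAV") < 10 || sum(rows$arm == "SAT") < 10) {
    abort("Each arm needs at least 10 records.")
  }
  x <- as.data.frame(covariate_matrix(rows, covariates))
  y <- rows[[outcome]]
  trt <- as.numeric(rows$arm == "CAV")

  folds <- with_seed(record_seed(seed, 57L), {
    f <- integer(nrow(rows))
    for (a in c(0, 1)) {
      idx <- which(trt == a)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  })

  oof <- function(target, salt) {
    pred <- numeric(length(target))
    for (fold in seq_len(k)) {
      hold <- folds == fold
      fit <- ranger::ranger(
        x = x[!hold, , drop = FALSE], y = target[!hold],
        num.trees = num_trees, seed = record_seed(seed, salt + fold),
        num.threads = 1
      )
      pred[hold] <- predict(
        fit, data = x[hold, , drop = FALSE], num.threads = 1
      )$predictions
    }
    pred
  }
  e_y <- y - oof(y, 200L)
  e_t <- trt - oof(trt, 300L)
  if (sum(e_t^2) < 1e-12) {
    abort("No residual treatment variation: treatment is fully predicted by covariates.")
  }
  if (intercept) {
    unname(coef(stats::lm(e_y ~ e_t))[2])
  } else {
    sum(e_y * e_t) / sum(e_t^2)
  }
}

#' Variable importance for an outcome on a matched sample
#'
#' Impurity-based importances from the two arm-specific T-learner forests,
#' averaged across arms and normalized to sum to one.
#'
#' @inheritParams t_learner
#' @return Tibble with `covariate`, `importance` (nonnegative, sums to 1).
#' @export
variable_importance <- function(matched, data, outcome,
                                covariates = dvt_covariates(), seed = 1L,
                                num_trees = 500) {
  ite <- t_learner(matched, data, outcome, covariates, seed = seed,
                   num_trees = num_trees)
  imp <- (attr(ite, "importance_treated") +
            attr(ite, "importance_control")) / 2
  imp <- pmax(imp, 0)
  tibble::tibble(
    covariate = names(imp),
    importance = unname(imp / sum(imp))
  )
}

#' Ensemble-weighted aggregate of per-method estimates
#'
#' The weighted average `sum_m w_m v_m` of one estimate per matching
#' method, using the composite ensemble weights. Method sets must coincide.
#'
#' @param per_method Named numeric vector of per-method estimates.
#' @param weights An `ensemble_weights` tibble or a named numeric vector.
#' @return A single number.
#' @export
#' @examples
#' weighted_aggregate(
#'   c(genetic = 2, mahalanobis = 4),
#'   c(genetic = 0.75, mahalanobis = 0.25)
#' )
weighted_aggregate <- function(per_method, weights) {
  if (inherits(weights, "ensemble_weights") || is.data.frame(weights)) {
    w <- setNames(weights$weight, weights$method)
  } else {
    w <- weights
  }
  if (is.null(names(per_method)) || is.null(names(w)) ||
      !setequal(names(per_method), names(w))) {
    abort("per_method and weights must cover the same named method set.")
  }
  sum(w[names(per_method)] * per_method)
}

#' Treatment-effect table across outcomes and matching methods
#'
#' For every outcome x method: T-learner ATE/ATT/ATC and the
#' double-residual estimate, plus one ensemble-weighted row per outcome
#' (the same weights aggregate all four estimands).
#'
#' @inheritParams cv_r2
#' @param matched_list Named list of `matched_dataset` objects.
#' @param weights An `ensemble_weights` object over the same methods.
#' @param dr Compute the double-residual column (default `TRUE`).
#' @return An `effect_table` tibble: `outcome`, `method`, `ate`, `att`,
#'   `atc`, `dr_effect`; methods plus a `"weighted"` row per outcome.
#' @export
effect_table <- function(matched_list, data, weights,
                         outcomes = dvt_outcomes(),
                         covariates = dvt_covariates(), seed = 1L,
                         num_trees = 500, k = 5, dr = TRUE) {
  out <- purrr::map_dfr(outcomes, function(oc) {
    per <- purrr::map_dfr(matched_list, function(m) {
      ite <- t_learner(m, data, oc, covariates, seed = seed,
                       num_trees = num_trees)
      eff <- treatment_effects(ite)
      eff$dr_effect <- if (dr) {
        double_residual(m, data, oc, covariates, k = k, seed = seed,
                        num_trees = num_trees)
      } else {
        NA_real_
      }
      method <- if (is.null(m)) "unmatched" else m$method
      dplyr::bind_cols(tibble::tibble(outcome = oc, method = method), eff)
    })
    if (!is.null(weights)) {
      wrow <- tibble::tibble(
        outcome = oc, method = "weighted",
        ate = weighted_aggregate(setNames(per$ate, per$method), weights),
        att = weighted_aggregate(setNames(per$att, per$method), weights),
        atc = weighted_aggregate(setNames(per$atc, per$method), weights),
        dr_effect = if (dr) {
          weighted_aggregate(setNames(per$dr_effect, per$method), weights)
        } else {
          NA_real_
        }
      )
      per <- dplyr::bind_rows(per, wrow)
    }
    per
  })
  structure(out, class = c("effect_table", class(out)))
}
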