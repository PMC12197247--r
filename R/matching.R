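# Four 1:1 matching algorithms without replacement: greedy nearest-neighbour
# on the logit propensity score within a caliper, greedy Mahalanobis
# distance, exact optimal assignment on the logit score within exact-match
# strata, and a genetic search over diagonal covariate weights.

new_matched_dataset <- function(method, treated_id, control_id,
                                n_treated_total, extra = list()) {
  if (length(treated_id) != length(control_id)) {
    abort("treated_id and control_id must have equal length.")
  }
  ids <- c(treated_id, control_id)
  if (anyDuplicated(ids) > 0) {
    abort("Matched pairs must be 1:1 without replacement (duplicate id).")
  }
  obj <- structure(
    list(
      method = method,
      pairs = tibble::tibble(
        pair = seq_along(treated_id),
        treated_id = treated_id,
        control_id = control_id
      ),
      retained_n = length(treated_id),
      n_treated_total = n_treated_total
    ),
    class = "matched_dataset"
  )
  obj[names(extra)] <- extra
  obj
}

# All record ids participating in the matched sample.
matched_ids <- function(matched) {
  c(matched$pairs$treated_id, matched$pairs$control_id)
}

#' @export
print.matched_dataset <- function(x, ...) {
  cat("Matched dataset [", x$method, "]: ", x$retained_n, " pairs (of ",
      x$n_treated_total, " treated)\n", sep = "")
  invisible(x)
}

#' Tidy/summarize a matched dataset
#'
#' `tidy()` returns the pair table; `glance()` a one-row summary with the
#' retention fraction used by the ensemble-weighting stage.
#'
#' @param x A `matched_dataset`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.matched_dataset <- function(x, ...) {
  x$pairs
}

#' @rdname tidy.matched_dataset
#' @exportS3Method generics::glance
#' @export
glance.matched_dataset <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_pairs = x$retained_n,
    n_treated_total = x$n_treated_total,
    retention = x$retained_n / x$n_treated_total
  )
}

# Greedy 1:1 selection on a treated x control distance matrix. Rows are
# visited in `row_order`; each takes the nearest still-unmatched control
# (columns must be sorted by ascending control id so which.min's first-hit
# rule breaks ties toward the smaller id). Inf entries are ineligible.
greedy_match_idx <- function(d, row_order) {
  n_c <- ncol(d)
  taken <- rep(FALSE, n_c)
  match_col <- rep(NA_integer_, nrow(d))
  for (i in row_order) {
    row <- d[i, ]
    row[taken] <- Inf
    j <- which.min(row)
    if (length(j) == 1 && is.finite(row[j])) {
      match_col[i] <- j
      taken[j] <- TRUE
    }
  }
  match_col
}

#' Nearest-neighbour propensity matching with a caliper
#'
#' Greedy 1:1 matching without replacement on the logit propensity score.
#' Treated records are processed in descending propensity order (hardest to
#' match first); a control is eligible only if its logit-score distance is
#' within `caliper_sd` pooled standard deviations of the logit score.
#' Unmatched treated records are dropped.
#'
#' @param model A [fit_propensity()] object.
#' @param caliper_sd Caliper width in SDs of the logit score (default 0.2).
#' @return A `matched_dataset`.
#' @export
match_nearest_caliper <- function(model, caliper_sd = 0.2) {
  if (caliper_sd <= 0) abort("caliper_sd must be positive.")
  lt <- model$logit_scores[model$arm == "CAV"]
  lc <- model$logit_scores[model$arm == "SAT"]
  lc <- lc[order(names(lc))]
  caliper <- caliper_sd * sd(model$logit_scores)
  d <- abs(outer(lt, lc, "-"))
  d[d > caliper] <- Inf
  row_order <- order(lt, decreasing = TRUE)
  mc <- greedy_match_idx(d, row_order)
  keep <- !is.na(mc)
  if (!any(keep)) {
    abort("No treated record found an eligible control within the caliper.")
  }
  new_matched_dataset(
    "nearest_caliper",
    treated_id = names(lt)[keep],
    control_id = names(lc)[mc[keep]],
    n_treated_total = length(lt),
    extra = list(caliper = unname(caliper))
  )
}

#' Mahalanobis distance matching
#'
#' Greedy 1:1 matching without replacement minimizing the Mahalanobis
#' distance on standardized covariates, using the pooled within-arm
#' covariance (ridge-regularized if near-singular). `cov_type = "diagonal"`
#' ignores cross-covariances, reducing the metric to weighted Euclidean
#' distance on z-scores.
#'
#' @param data Cohort tibble.
#' @param covariates Covariate names; default [dvt_covariates()].
#' @param cov_type `"pooled"` (full matrix) or `"diagonal"`.
#' @return A `matched_dataset`.
#' @export
match_mahalanobis <- function(data, covariates = dvt_covariates(),
                              cov_type = c("pooled", "diagonal")) {
  cov_type <- match.arg(cov_type)
  assert_cohort_columns(data, c("id", "arm"))
  x <- covariate_matrix(data, covariates)
  z <- standardize_columns(x)
  is_t <- data$arm == "CAV"
  zt <- z[is_t, , drop = FALSE]
  zc <- z[!is_t, , drop = FALSE]
  s <- pooled_within_cov(zt, zc)
  if (cov_type == "diagonal") s <- diag(diag(s), ncol(s))
  r <- tryCatch(chol(s), error = function(e) NULL)
  if (is.null(r)) {
    s <- s + diag(1e-6 * mean(diag(s)), ncol(s))
    r <- tryCatch(chol(s), error = function(e) NULL)
  }
  if (is.null(r)) {
    qr_z <- qr(z)
    collinear <- colnames(z)[qr_z$pivot[seq.int(qr_z$rank + 1, ncol(z))]]
    abort(paste0("Covariance matrix singular after regularization; ",
                 "collinear covariates: ", paste(collinear, collapse = ", ")))
  }
  # S^{-1} = R^{-1} R^{-T}: Euclidean distance after x %*% R^{-1}.
  rinv <- backsolve(r, diag(ncol(z)))
  tt <- zt %*% rinv
  tc <- zc %*% rinv
  ord <- order(rownames(tc))
  tc <- tc[ord, , drop = FALSE]
  d2 <- outer(rowSums(tt^2), rep(1, nrow(tc))) +
    outer(rep(1, nrow(tt)), rowSums(tc^2)) - 2 * tcrossprod(tt, tc)
  row_order <- order(rownames(tt))
  mc <- greedy_match_idx(d2, row_order)
  keep <- !is.na(mc)
  if (!any(keep)) abort("No pairs could be formed.")
  new_matched_dataset(
    "mahalanobis",
    treated_id = rownames(tt)[keep],
    control_id = rownames(tc)[mc[keep]],
    n_treated_total = nrow(tt)
  )
}

pooled_within_cov <- function(zt, zc) {
  nt <- nrow(zt)
  nc_ <- nrow(zc)
  st <- if (nt > 1) cov(zt) else matrix(0, ncol(zt), ncol(zt))
  sc <- if (nc_ > 1) cov(zc) else matrix(0, ncol(zc), ncol(zc))
  ((nt - 1) * st + (nc_ - 1) * sc) / max(nt + nc_ - 2, 1)
}

# Exact minimum-total-cost 1:1 assignment of m treated to n >= m controls
# on the real line (costs |t_i - c_j|). With sorted inputs an optimal
# assignment is non-crossing, so a two-index dynamic program is exact.
assign_optimal_1d <- function(tv, cv) {
  m <- length(tv)
  n <- length(cv)
  if (m > n) abort("Need at least as many controls as treated.")
  ot <- order(tv)
  oc <- order(cv)
  ts <- tv[ot]
  cs <- cv[oc]
  dp <- matrix(Inf, m + 1, n + 1)
  dp[1, ] <- 0
  for (i in seq_len(m)) {
    for (j in i:n) {
      stay <- dp[i + 1, j]               # control j unused
      take <- dp[i, j] + abs(ts[i] - cs[j])
      dp[i + 1, j + 1] <- min(stay, take)
    }
  }
  # Backtrack (prefer "take" on ties for determinism).
  assign_sorted <- integer(m)
  i <- m
  j <- n
  while (i >= 1) {
    take <- dp[i, j] + abs(ts[i] - cs[j])
    if (j > i && dp[i + 1, j] < take) {
      j <- j - 1
    } else {
      assign_sorted[i] <- j
      i <- i - 1
      j <- j - 1
    }
  }
  assignment <- integer(m)
  assignment[ot] <- oc[assign_sorted]
  list(assignment = assignment, total = dp[m + 1, n + 1])
}

#' Optimal propensity matching with exact constraints
#'
#' Minimum-total-|logit propensity distance| 1:1 assignment, solved exactly,
#' within strata defined by the exact-match variables (default gender, so
#' every pair shares gender). A stratum with fewer controls than treated is
#' relaxed with a warning: its treated records are assigned optimally
#' against the controls left over after all feasible strata are matched.
#' All treated records are retained whenever feasible.
#'
#' @param model A [fit_propensity()] object.
#' @param data Cohort tibble (supplies the exact-match variables).
#' @param exact_vars Column names matched exactly; default `"gender"`.
#' @return A `matched_dataset`.
#' @export
match_optimal_exact <- function(model, data, exact_vars = "gender") {
  assert_cohort_columns(data, c("id", exact_vars))
  strata <- interaction(data[exact_vars], drop = TRUE)
  stratum_of <- setNames(as.character(strata), data$id)
  lt <- model$logit_scores[model$arm == "CAV"]
  lc <- model$logit_scores[model$arm == "SAT"]
  used <- character(0)
  pairs_t <- character(0)
  pairs_c <- character(0)
  relaxed <- character(0)
  for (s in unique(stratum_of[names(lt)])) {
    t_ids <- names(lt)[stratum_of[names(lt)] == s]
    c_ids <- names(lc)[stratum_of[names(lc)] == s]
    if (length(c_ids) < length(t_ids)) {
      warn(paste0("Stratum '", s, "' has ", length(c_ids), " controls for ",
                  length(t_ids), " treated; exact constraint relaxed."))
      relaxed <- c(relaxed, t_ids)
      next
    }
    sol <- assign_optimal_1d(lt[t_ids], lc[c_ids])
    pairs_t <- c(pairs_t, t_ids)
    pairs_c <- c(pairs_c, c_ids[sol$assignment])
    used <- c(used, c_ids[sol$assignment])
  }
  if (length(relaxed) > 0) {
    free_c <- setdiff(names(lc), used)
    if (length(free_c) < length(relaxed)) {
      abort("Infeasible matching: not enough controls even after relaxing strata.")
    }
    sol <- assign_optimal_1d(lt[relaxed], lc[free_c])
    pairs_t <- c(pairs_t, relaxed)
    pairs_c <- c(pairs_c, free_c[sol$assignment])
  }
  ord <- order(pairs_t)
  new_matched_dataset(
    "optimal_exact",
    treated_id = pairs_t[ord],
    control_id = pairs_c[ord],
    n_treated_total = length(lt),
    extra = list(exact_vars = exact_vars)
  )
}

# Per-covariate SMD of a candidate match, on the raw covariate matrix.
match_smds <- function(x, covariates, t_ids, c_ids) {
  vapply(covariates, function(nm) {
    kind <- if (nm == "gender") "binary" else "continuous"
    smd(x[t_ids, nm], x[c_ids, nm], kind = kind)
  }, numeric(1))
}

#' Genetic matching: evolutionary search over covariate weights
#'
#' Searches positive diagonal weight vectors `w` for the generalized
#' distance `sqrt(sum_j w_j (z_tj - z_cj)^2)`; each candidate induces a
#' greedy 1:1 match, scored by post-match balance. Fitness minimizes the
#' maximum covariate SMD with the mean SMD as tie-break. The population
#' always contains the equal-weights vector (so the result can never score
#' worse than unweighted Euclidean matching), plus any user-supplied
#' starting weights and random log-normal perturbations. Reproducible for a
#' fixed seed; `generations = 0` evaluates only the initial population.
#'
#' @param data Cohort tibble.
#' @param covariates Covariate names; default [dvt_covariates()].
#' @param generations Number of evolutionary generations (>= 0).
#' @param pop_size Population size (>= 1).
#' @param seed Integer seed.
#' @param init_weights Optional matrix (rows = weight vectors) to seed the
#'   initial population.
#' @return A `matched_dataset` with the winning `weights` attached.
#' @export
match_genetic <- function(data, covariates = dvt_covariates(),
                          generations = 20, pop_size = 30, seed = 1L,
                          init_weights = NULL) {
  if (pop_size < 1) abort("pop_size must be >= 1.")
  if (generations < 0) abort("generations must be >= 0.")
  assert_cohort_columns(data, c("id", "arm"))
  x <- covariate_matrix(data, covariates)
  z <- standardize_columns(x)
  is_t <- data$arm == "CAV"
  zt <- z[is_t, , drop = FALSE]
  zc <- z[!is_t, , drop = FALSE]
  ord_c <- order(rownames(zc))
  zc <- zc[ord_c, , drop = FALSE]
  row_order <- order(rownames(zt))
  k <- ncol(z)

  eval_candidate <- function(w) {
    w <- w / mean(w)  # scale-free metric; normalize for numeric stability
    d2 <- outer(drop(zt^2 %*% w), rep(1, nrow(zc))) +
      outer(rep(1, nrow(zt)), drop(zc^2 %*% w)) -
      2 * tcrossprod(sweep(zt, 2, w, "*"), zc)
    mc <- greedy_match_idx(d2, row_order)
    keep <- !is.na(mc)
    t_ids <- rownames(zt)[keep]
    c_ids <- rownames(zc)[mc[keep]]
    smds <- match_smds(x, covariates, t_ids, c_ids)
    list(w = w, t_ids = t_ids, c_ids = c_ids,
         max_smd = max(smds), mean_smd = mean(smds))
  }
  better <- function(a, b) {
    a$max_smd < b$max_smd - 1e-12 ||
      (abs(a$max_smd - b$max_smd) <= 1e-12 && a$mean_smd < b$mean_smd)
  }

  with_seed(record_seed(seed, 424243L), {
    pop <- list(rep(1, k))
    if (!is.null(init_weights)) {
      for (i in seq_len(nrow(init_weights))) {
        pop[[length(pop) + 1]] <- as.numeric(init_weights[i, ])
      }
    }
    while (length(pop) < pop_size) {
      pop[[length(pop) + 1]] <- exp(stats::rnorm(k, 0, 0.5))
    }
    pop <- pop[seq_len(max(pop_size, length(pop)))]

    scored <- lapply(pop, eval_candidate)
    best <- scored[[1]]
    for (s in scored) if (better(s, best)) best <- s

    gen <- 0
    while (gen < generations) {
      gen <- gen + 1
      ranks <- order(
        vapply(scored, `[[`, numeric(1), "max_smd"),
        vapply(scored, `[[`, numeric(1), "mean_smd")
      )
      n_elite <- max(2, ceiling(length(scored) / 4))
      elite <- scored[ranks[seq_len(min(n_elite, length(scored)))]]
      children <- list()
      while (length(children) < length(pop) - length(elite)) {
        pa <- elite[[sample.int(length(elite), 1)]]$w
        pb <- elite[[sample.int(length(elite), 1)]]$w
        child <- sqrt(pa * pb) * exp(stats::rnorm(k, 0, 0.35))
        children[[length(children) + 1]] <- child
      }
      scored <- c(elite, lapply(children, eval_candidate))
      for (s in scored) if (better(s, best)) best <- s
    }

    new_matched_dataset(
      "genetic",
      treated_id = best$t_ids,
      control_id = best$c_ids,
      n_treated_total = nrow(zt),
      extra = list(weights = setNames(best$w, covariates),
                   fitness = c(max_smd = best$max_smd,
                               mean_smd = best$mean_smd))
    )
  })
}
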