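# The four matching algorithms: greedy caliper, Mahalanobis, exact optimal
# assignment, genetic weight search.

test_that("caliper matching picks the nearest in-caliper control", {
  model <- fake_model(
    setNames(c(0.0, 0.4, 0.1), c("t1", "c1", "c2")),
    c("CAV", "SAT", "SAT")
  )
  # caliper distance 0.2: c2 (|0.1|) eligible, c1 (|0.4|) not
  m <- match_nearest_caliper(model, caliper_sd = 0.2 / sd(c(0, 0.4, 0.1)))
  expect_equal(m$pairs$treated_id, "t1")
  expect_equal(m$pairs$control_id, "c2")
})

test_that("treated with no in-caliper control are dropped; none matched errors", {
  model <- fake_model(
    setNames(c(0.0, 5.0, 0.05, 10.0), c("t1", "t2", "c1", "c2")),
    c("CAV", "CAV", "SAT", "SAT")
  )
  m <- match_nearest_caliper(model, caliper_sd = 0.05)
  expect_equal(m$pairs$treated_id, "t1")
  expect_equal(m$retained_n, 1)
  expect_equal(m$n_treated_total, 2)

  lonely <- fake_model(setNames(c(0, 3), c("t1", "c1")), c("CAV", "SAT"))
  expect_error(match_nearest_caliper(lonely, caliper_sd = 0.01),
               "caliper")
})

test_that("every caliper pair satisfies the caliper bound", {
  cohort <- generate_cohort(cohort_params(n_total = 300, seed = 31))
  model <- fit_propensity(cohort)
  m <- match_nearest_caliper(model, caliper_sd = 0.2)
  gap <- abs(model$logit_scores[m$pairs$treated_id] -
               model$logit_scores[m$pairs$control_id])
  expect_true(all(gap <= m$caliper + 1e-12))
})

test_that("a tight caliper retains fewer pairs than the treated arm", {
  cohort <- generate_cohort(cohort_params(n_total = 396, seed = 32))
  model <- fit_propensity(cohort)
  m <- match_nearest_caliper(model, caliper_sd = 0.05)
  expect_lt(m$retained_n, m$n_treated_total)
})

test_that("one-covariate Mahalanobis reduces to nearest neighbour on z", {
  cohort <- manual_cohort(8, arm = c(rep("CAV", 3), rep("SAT", 5)))
  cohort$aptt <- c(30, 40, 25, 29.5, 41, 24, 50, 33)
  m <- match_mahalanobis(cohort, covariates = "aptt")
  got <- setNames(m$pairs$control_id, m$pairs$treated_id)
  # treated visited in id order: 30 -> 29.5, 40 -> 41, 25 -> 24
  expect_equal(unname(got[cohort$id[1:3]]),
               cohort$id[c(4, 5, 6)])
})

test_that("identical covariate rows give zero-distance pairs first", {
  base <- manual_cohort(6, arm = rep("CAV", 6))
  clone <- base
  clone$id <- sprintf("C%04d", 1:6)
  clone$arm <- "SAT"
  cohort <- rbind(base, clone)
  m <- match_mahalanobis(cohort)
  expect_equal(m$pairs$control_id, clone$id[match(m$pairs$treated_id, base$id)])
})

test_that("greedy Mahalanobis choice equals a brute-force greedy oracle", {
  cohort <- manual_cohort(4, arm = c("CAV", "CAV", "SAT", "SAT"))
  cohort$aptt <- c(30, 34, 31, 36)
  cohort$plt <- c(150, 180, 160, 170)
  m <- match_mahalanobis(cohort, covariates = c("aptt", "plt"))
  # Oracle: compute the 2x2 Mahalanobis distance matrix directly.
  z <- dvtmatch:::standardize_columns(
    dvtmatch:::covariate_matrix(cohort, c("aptt", "plt"))
  )
  s <- dvtmatch:::pooled_within_cov(z[1:2, ], z[3:4, ])
  si <- solve(s)
  d <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    v <- z[i, ] - z[j + 2, ]
    d[i, j] <- drop(t(v) %*% si %*% v)
  }
  # greedy in treated id order
  j1 <- which.min(d[1, ])
  j2 <- setdiff(1:2, j1)
  expect_equal(m$pairs$control_id[m$pairs$treated_id == cohort$id[1]],
               cohort$id[2 + j1])
  expect_equal(m$pairs$control_id[m$pairs$treated_id == cohort$id[2]],
               cohort$id[2 + j2])
})

test_that("optimal assignment beats greedy on the classic 2x2 instance", {
  tv <- c(0.4, 0.5)
  cv <- c(0.45, 0.0)
  sol <- dvtmatch:::assign_optimal_1d(tv, cv)
  expect_equal(sol$total, 0.45, tolerance = 1e-12)
  expect_equal(greedy_total_1d(tv, cv), 0.55, tolerance = 1e-12)
  expect_lt(sol$total, greedy_total_1d(tv, cv))
  # 0.4 -> 0.0 and 0.5 -> 0.45
  expect_equal(sol$assignment, c(2, 1))
})

test_that("exact constraints are honored and feasible strata keep all treated", {
  cohort <- generate_cohort(cohort_params(n_total = 396, seed = 33))
  model <- fit_propensity(cohort)
  m <- match_optimal_exact(model, cohort, exact_vars = "gender")
  g <- setNames(cohort$gender, cohort$id)
  expect_true(all(g[m$pairs$treated_id] == g[m$pairs$control_id]))
  expect_equal(m$retained_n, sum(cohort$arm == "CAV"))
})

test_that("infeasible strata are relaxed with a warning", {
  cohort <- manual_cohort(8, arm = c(rep("CAV", 3), rep("SAT", 5)),
                          gender = c("F", "F", "M", rep("F", 5)))
  model <- suppressWarnings(fit_propensity(cohort, covariates = "aptt"))
  expect_warning(m <- match_optimal_exact(model, cohort, "gender"),
                 "relaxed")
  expect_equal(m$retained_n, 3)
})

test_that("genetic search with a degenerate population equals diagonal Mahalanobis", {
  cohort <- manual_cohort(12, arm = rep(c("CAV", "SAT", "SAT"), 4))
  cohort$aptt <- c(30, 29, 35, 40, 42, 38, 25, 27, 24, 33, 31, 36)
  mg <- match_genetic(cohort, covariates = "aptt", generations = 0,
                      pop_size = 1, seed = 1)
  mm <- match_mahalanobis(cohort, covariates = "aptt",
                          cov_type = "diagonal")
  expect_equal(mg$pairs$treated_id, mm$pairs$treated_id)
  expect_equal(mg$pairs$control_id, mm$pairs$control_id)
})

test_that("genetic search never scores worse than equal weights", {
  cohort <- generate_cohort(cohort_params(n_total = 200, seed = 34))
  equal <- match_genetic(cohort, generations = 0, pop_size = 1, seed = 1)
  searched <- match_genetic(cohort, generations = 3, pop_size = 8, seed = 1)
  expect_lte(searched$fitness[["max_smd"]], equal$fitness[["max_smd"]] + 1e-12)
})

test_that("genetic result matches a grid-search oracle on a tiny instance", {
  cohort <- manual_cohort(8, arm = c(rep("CAV", 3), rep("SAT", 5)))
  cohort$aptt <- c(30, 36, 28, 29, 37, 31, 26, 41)
  cohort$plt <- c(150, 190, 140, 160, 185, 120, 150, 200)
  grid <- as.matrix(expand.grid(c(0.25, 0.5, 1, 2, 4), c(0.25, 0.5, 1, 2, 4)))
  best_grid <- Inf
  for (i in seq_len(nrow(grid))) {
    m <- match_genetic(cohort, covariates = c("aptt", "plt"),
                       generations = 0, pop_size = 1, seed = 1,
                       init_weights = grid[i, , drop = FALSE])
    best_grid <- min(best_grid, m$fitness[["max_smd"]])
  }
  gm <- match_genetic(cohort, covariates = c("aptt", "plt"),
                      generations = 0, pop_size = 2, seed = 1,
                      init_weights = grid)
  expect_lte(gm$fitness[["max_smd"]], best_grid + 1e-9)
})

test_that("all methods produce disjoint 1:1 pairs with treated from CAV", {
  cohort <- generate_cohort(cohort_params(n_total = 300, seed = 35))
  model <- fit_propensity(cohort)
  arm_of <- setNames(cohort$arm, cohort$id)
  methods <- list(
    match_nearest_caliper(model),
    match_mahalanobis(cohort),
    match_optimal_exact(model, cohort),
    match_genetic(cohort, generations = 1, pop_size = 4, seed = 2)
  )
  for (m in methods) {
    ids <- c(m$pairs$treated_id, m$pairs$control_id)
    expect_equal(anyDuplicated(ids), 0)
    expect_true(all(arm_of[m$pairs$treated_id] == "CAV"))
    expect_true(all(arm_of[m$pairs$control_id] == "SAT"))
    expect_equal(length(m$pairs$treated_id), length(m$pairs$control_id))
  }
})

test_that("optimal total distance never exceeds greedy on random instances", {
  set.seed(99)
  for (rep in 1:100) {
    m <- sample(2:6, 1)
    n <- m + sample(0:5, 1)
    tv <- runif(m)
    cv <- runif(n)
    sol <- dvtmatch:::assign_optimal_1d(tv, cv)
    expect_lte(sol$total, greedy_total_1d(tv, cv) + 1e-12)
    # cross-check tiny cases against brute-force enumeration
    if (n <= 5) {
      perms <- all_assignments(n, m)
      brute <- min(apply(perms, 1, function(p) sum(abs(tv - cv[p]))))
      expect_equal(sol$total, brute, tolerance = 1e-12)
    }
  }
})

test_that("matching reduces mean SMD on confounded cohorts almost always", {
  wins <- c(caliper = 0, mahalanobis = 0, optimal = 0, genetic = 0)
  n_rep <- 25
  for (seed in seq_len(n_rep)) {
    cohort <- generate_cohort(cohort_params(n_total = 400, seed = 200 + seed))
    model <- fit_propensity(cohort)
    pre <- mean(dvtmatch:::smd_profile(cohort, dvt_covariates(),
                                       cohort$id[cohort$arm == "CAV"],
                                       cohort$id[cohort$arm == "SAT"]))
    ms <- list(
      caliper = match_nearest_caliper(model),
      mahalanobis = match_mahalanobis(cohort),
      optimal = match_optimal_exact(model, cohort),
      genetic = match_genetic(cohort, generations = 2, pop_size = 6,
                              seed = seed)
    )
    for (nm in names(ms)) {
      post <- attr(balance_report(cohort, ms[[nm]]), "mean_smd")
      wins[[nm]] <- wins[[nm]] + (post <= pre)
    }
  }
  for (nm in names(wins)) expect_gte(wins[[nm]] / n_rep, 0.9)
})
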