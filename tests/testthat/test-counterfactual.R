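# T-learner counterfactuals, effect decomposition, the double-residual
# estimator, variable importance, and weighted aggregation.

test_that("a constant outcome yields all-zero ITEs", {
  cohort <- manual_cohort(60, arm = rep(c("CAV", "SAT"), 30), seed = 61)
  cohort$ipr <- 42
  ite <- t_learner(full_pairing(cohort), cohort, "ipr", num_trees = 50)
  expect_equal(ite$y1_hat, rep(42, 60))
  expect_equal(ite$y0_hat, rep(42, 60))
  expect_equal(ite$ite, rep(0, 60))
})

test_that("a pure additive arm effect is recovered", {
  cohort <- manual_cohort(400, arm = rep(c("CAV", "SAT"), 200), seed = 62)
  cohort$ipr <- 2 * (cohort$arm == "CAV")
  ite <- t_learner(full_pairing(cohort), cohort, "ipr", seed = 3,
                   num_trees = 200)
  expect_gte(mean(ite$ite), 1.8)
  expect_lte(mean(ite$ite), 2.2)
})

test_that("ITEs are invariant to data row order for a fixed seed", {
  cohort <- manual_cohort(80, arm = rep(c("CAV", "SAT"), 40), seed = 63)
  cohort$ipr <- cohort$aptt + stats::rnorm(80)
  matched <- full_pairing(cohort)
  a <- t_learner(matched, cohort, "ipr", seed = 5, num_trees = 100)
  b <- t_learner(matched, cohort[rev(seq_len(80)), ], "ipr", seed = 5,
                 num_trees = 100)
  expect_equal(a$ite, b$ite, tolerance = 1e-10)
})

test_that("small arms are rejected with the arm named", {
  cohort <- manual_cohort(24, arm = c(rep("CAV", 4), rep("SAT", 20)))
  matched <- make_matched(cohort$id[1:4], cohort$id[5:8])
  expect_error(t_learner(matched, cohort, "score_day1"), "Treated")
})

test_that("effects match hand arithmetic and the decomposition identity", {
  ite <- tibble::tibble(arm = c("CAV", "CAV", "SAT", "SAT"),
                        ite = c(1, 2, 3, 4))
  eff <- treatment_effects(ite)
  expect_equal(eff$ate, 2.5)
  expect_equal(eff$att, 1.5)
  expect_equal(eff$atc, 3.5)

  const <- tibble::tibble(arm = rep(c("CAV", "SAT"), 5), ite = rep(7, 10))
  effc <- treatment_effects(const)
  expect_equal(unlist(effc), c(ate = 7, att = 7, atc = 7))

  set.seed(9)
  rnd <- tibble::tibble(arm = sample(c("CAV", "SAT"), 57, replace = TRUE),
                        ite = stats::rnorm(57))
  e <- treatment_effects(rnd)
  n_t <- sum(rnd$arm == "CAV")
  n_c <- 57 - n_t
  expect_equal(e$ate, (n_t * e$att + n_c * e$atc) / 57, tolerance = 1e-12)
})

test_that("double residual recovers a randomized additive effect", {
  set.seed(71)
  cohort <- manual_cohort(500, arm = sample(rep(c("CAV", "SAT"), 250)),
                          seed = 71)
  cohort$ipr <- 3 * (cohort$arm == "CAV") + stats::rnorm(500)
  dr <- double_residual(NULL, cohort, "ipr", seed = 2, num_trees = 150)
  expect_gte(dr, 2.7)
  expect_lte(dr, 3.3)
})

test_that("double residual is near zero under the null", {
  ests <- vapply(1:12, function(s) {
    cohort <- manual_cohort(300, arm = rep(c("CAV", "SAT"), 150), seed = s)
    set.seed(s)
    cohort$ipr <- stats::rnorm(300)
    double_residual(full_pairing(cohort), cohort, "ipr", seed = s,
                    num_trees = 100)
  }, numeric(1))
  expect_lt(abs(mean(ests)), 3 * sd(ests) / sqrt(length(ests)))
})

test_that("double residual deconfounds a covariate-driven null effect", {
  better <- 0
  n_rep <- 20
  for (s in seq_len(n_rep)) {
    set.seed(400 + s)
    n <- 300
    x <- stats::rnorm(n)
    arm <- ifelse(stats::runif(n) < plogis(1.5 * x), "CAV", "SAT")
    if (sum(arm == "CAV") < 20 || sum(arm == "SAT") < 20) next
    cohort <- manual_cohort(n, arm = arm, seed = s)
    cohort$aptt <- 32 + 5 * x
    cohort$ipr <- 4 * x + stats::rnorm(n)  # true treatment effect is zero
    dr <- double_residual(NULL, cohort, "ipr", seed = s, num_trees = 100)
    naive <- mean(cohort$ipr[arm == "CAV"]) - mean(cohort$ipr[arm == "SAT"])
    better <- better + (abs(dr) < abs(naive))
  }
  expect_gte(better / n_rep, 0.9)
})

test_that("treatment fully predicted by covariates raises a clear error", {
  cohort <- manual_cohort(60, arm = c(rep("CAV", 30), rep("SAT", 30)),
                          seed = 64)
  cohort$aptt <- ifelse(cohort$arm == "CAV", 20, 45)
  cohort$ipr <- stats::rnorm(60)
  expect_error(
    double_residual(full_pairing(cohort), cohort, "ipr",
                    covariates = "aptt", num_trees = 100),
    "residual treatment variation"
  )
})

test_that("variable importance finds the driving covariate and normalizes", {
  cohort <- manual_cohort(300, arm = rep(c("CAV", "SAT"), 150), seed = 65)
  cohort$ipr <- 3 * cohort$aptt + stats::rnorm(300, sd = 0.5)
  imp <- variable_importance(full_pairing(cohort), cohort, "ipr",
                             num_trees = 200)
  expect_equal(imp$covariate[which.max(imp$importance)], "aptt")
  expect_equal(sum(imp$importance), 1, tolerance = 1e-12)
  expect_true(all(imp$importance >= 0))
})

test_that("all-noise covariates give roughly uniform importance", {
  cohort <- manual_cohort(1000, arm = rep(c("CAV", "SAT"), 500), seed = 66)
  set.seed(13)
  for (nm in setdiff(dvt_covariates(), "gender")) {
    cohort[[nm]] <- stats::rnorm(1000)
  }
  cohort$ipr <- stats::rnorm(1000)
  imp <- variable_importance(full_pairing(cohort), cohort, "ipr",
                             covariates = setdiff(dvt_covariates(), "gender"),
                             num_trees = 200)
  expect_lt(max(imp$importance) / min(imp$importance), 5)
})

test_that("weighted aggregation reproduces the published weighted average", {
  ref <- reference_effects()
  ipr <- ref[ref$outcome == "ipr" & ref$method != "weighted", ]
  agg <- weighted_aggregate(setNames(ipr$ate, ipr$method),
                            reference_weights())
  expect_equal(agg, 6.390419, tolerance = 6.390419 * 5e-4)
})

test_that("weighted aggregation is linear with unit and degenerate weights", {
  v <- c(genetic = 2, mahalanobis = 2, nearest_caliper = 2, optimal_exact = 2)
  w <- c(genetic = 0.1, mahalanobis = 0.2, nearest_caliper = 0.3,
         optimal_exact = 0.4)
  expect_equal(weighted_aggregate(v, w), 2)
  w1 <- c(genetic = 1, mahalanobis = 0, nearest_caliper = 0,
          optimal_exact = 0)
  u <- c(genetic = 5, mahalanobis = -1, nearest_caliper = 0,
         optimal_exact = 100)
  expect_equal(weighted_aggregate(u, w1), 5)
  expect_equal(weighted_aggregate(2 * u + 3 * v, w),
               2 * weighted_aggregate(u, w) + 3 * weighted_aggregate(v, w),
               tolerance = 1e-12)
  expect_error(weighted_aggregate(u[-1], w), "method set")
})
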