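# Synthetic cohort generator: reproducibility, calibration, confounding
# structure and the Monte-Carlo ground-truth oracle.

test_that("fixed seed reproduces the cohort byte-for-byte", {
  p <- cohort_params(n_total = 80, seed = 11)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a, b)
  fa <- tempfile(fileext = ".csv")
  fb <- tempfile(fileext = ".csv")
  write_cohort(a, fa)
  write_cohort(b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
})

test_that("per-record substreams: extending the cohort keeps earlier records", {
  small <- generate_cohort(cohort_params(n_total = 40, seed = 7))
  large <- generate_cohort(cohort_params(n_total = 60, seed = 7))
  cols <- setdiff(names(small), "id")
  expect_identical(plain_df(small[, cols]),
                   plain_df(large[seq_len(40), cols]))
})

test_that("zero propensity slopes give an unconfounded 50/50 assignment", {
  p <- cohort_params(
    n_total = 10000, treated_fraction = 0.5,
    propensity = list(intercept = "auto", slopes = numeric(0)),
    seed = 2
  )
  cohort <- generate_cohort(p)
  share <- mean(cohort$arm == "CAV")
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(share - 0.5), 3 * se)
})

test_that("unconfounded assignment balances covariates (SMD -> 0)", {
  for (seed in 1:5) {
    p <- cohort_params(
      n_total = 10000, treated_fraction = 0.5,
      propensity = list(intercept = "auto", slopes = numeric(0)),
      seed = seed
    )
    cohort <- generate_cohort(p)
    smds <- dvtmatch:::smd_profile(cohort, dvt_covariates(),
                                   cohort$id[cohort$arm == "CAV"],
                                   cohort$id[cohort$arm == "SAT"])
    expect_lt(max(smds), 0.05)
  }
})

test_that("observed outcomes equal the assigned arm's potential outcomes", {
  cohort <- generate_cohort(cohort_params(n_total = 300, seed = 9))
  cav <- cohort$arm == "CAV"
  expect_identical(cohort$score_discharge,
                   ifelse(cav, cohort$po_score_discharge_cav,
                          cohort$po_score_discharge_sat))
  expect_identical(cohort$los_days,
                   ifelse(cav, cohort$po_los_cav, cohort$po_los_sat))
  expect_identical(cohort$cost_cny,
                   ifelse(cav, cohort$po_cost_cav, cohort$po_cost_sat))
})

test_that("SAT-arm APTT median matches the published calibration window", {
  for (seed in 1:20) {
    cohort <- generate_cohort(cohort_params(n_total = 396, seed = seed))
    sat_aptt <- median(cohort$aptt[cohort$arm == "SAT"])
    expect_gte(sat_aptt, 30)
    expect_lte(sat_aptt, 36)
  }
})

test_that("confounding slopes shift the treated arm in the stated directions", {
  cohort <- generate_cohort(cohort_params(n_total = 5000, seed = 4))
  cav <- cohort$arm == "CAV"
  expect_lt(median(cohort$aptt[cav]), median(cohort$aptt[!cav]))
  expect_lt(median(cohort$wbc[cav]), median(cohort$wbc[!cav]))
  expect_gt(median(cohort$tt[cav]), median(cohort$tt[!cav]))
  expect_gt(mean(cohort$gender[cav] == "M"), mean(cohort$gender[!cav] == "M"))
})

test_that("degenerate assignment errors and names the coefficients", {
  p <- cohort_params(
    n_total = 50,
    propensity = list(intercept = 40, slopes = c(aptt = -0.8)),
    seed = 1
  )
  expect_error(generate_cohort(p), "Degenerate.*aptt")
})

test_that("null effects give a ground truth of exactly zero", {
  p <- cohort_params(n_total = 100, ipr_effect_pp = 0, los_effect_days = 0,
                     cost_log_ratio = 0, seed = 3)
  gt <- ground_truth(p, n_mc = 10000)
  expect_true(all(abs(gt$effects$effect) <= 3 * gt$effects$se + 1e-12))
  expect_equal(gt$effects$effect, rep(0, 6), tolerance = 1e-12)
})

test_that("a forced 2-point extra reduction on day1 = 10 is +20pp of IPR", {
  om <- default_outcome_model(ipr_effect_pp = 0, los_effect_days = 0,
                              cost_log_ratio = 0)
  om$day1$baseline <- function(v) rep(10, nrow(v))
  om$day1$sd <- 0
  om$discharge$baseline <- function(v, day1) rep(5, length(day1))
  om$discharge$sd <- 0.5
  om$discharge$effect <- -2
  p <- cohort_params(n_total = 100, outcome_model = om,
                     exclusion_rate = 0, seed = 6)
  gt <- ground_truth(p, n_mc = 10000)
  expect_equal(gt$effects$effect[gt$effects$metric == "ipr"], 20,
               tolerance = 1e-9)
  expect_equal(gt$effects$effect[gt$effects$metric == "los"], 0,
               tolerance = 1e-12)
})

test_that("default calibration injects an IPR effect near 6.4pp", {
  gt <- ground_truth(cohort_params(seed = 12), n_mc = 20000)
  ipr <- gt$effects$effect[gt$effects$metric == "ipr"]
  expect_gt(ipr, 6.1)
  expect_lt(ipr, 6.6)
  los <- gt$effects$effect[gt$effects$metric == "los"]
  expect_equal(los, 0.15, tolerance = 1e-6)
})

test_that("ground truth is invariant to the treated fraction", {
  p1 <- cohort_params(n_total = 100, treated_fraction = 0.12, seed = 5)
  p2 <- cohort_params(n_total = 100, treated_fraction = 0.45, seed = 5)
  expect_identical(ground_truth(p1, n_mc = 10000)$effects,
                   ground_truth(p2, n_mc = 10000)$effects)
})

test_that("an optional copula correlation induces covariate correlation", {
  cm <- matrix(c(1, 0.7, 0.7, 1), 2, 2,
               dimnames = list(c("aptt", "tt"), c("aptt", "tt")))
  p <- cohort_params(n_total = 2000, correlation = cm, seed = 8)
  cohort <- generate_cohort(p)
  expect_gt(cor(cohort$aptt, cohort$tt, method = "spearman"), 0.55)
  indep <- generate_cohort(cohort_params(n_total = 2000, seed = 8))
  expect_lt(abs(cor(indep$aptt, indep$tt, method = "spearman")), 0.1)
})
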