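# Programmatic fixtures: controlled cohorts, hand-built matched sets, and
# small independent oracles used to pin expected values.

# A fully manual cohort with valid schema columns. Covariates get mild
# deterministic jitter so nothing is constant unless overridden.
manual_cohort <- function(n, arm = rep(c("CAV", "SAT"), length.out = n),
                          seed = 1, ...) {
  jitter_col <- function(center, spread, salt) {
    set.seed(seed + salt)
    center + spread * stats::runif(n, -1, 1)
  }
  out <- tibble::tibble(
    id = sprintf("T%04d", seq_len(n)),
    arm = arm,
    gender = rep(c("F", "M"), length.out = n),
    age = jitter_col(60, 10, 1),
    height_cm = jitter_col(165, 8, 2),
    weight_kg = jitter_col(65, 9, 3),
    wells = jitter_col(4, 1.5, 4),
    wbc = jitter_col(9, 2, 5),
    rbc = jitter_col(5, 0.4, 6),
    hgb = jitter_col(15, 1, 7),
    plt = jitter_col(160, 40, 8),
    hct = jitter_col(45, 1, 9),
    pt = jitter_col(13, 1.5, 10),
    inr = jitter_col(1.1, 0.1, 11),
    aptt = jitter_col(32, 5, 12),
    tt = jitter_col(25, 3, 13),
    fib = jitter_col(3.5, 0.5, 14),
    ddimer = jitter_col(11, 4, 15),
    fdp = jitter_col(20, 6, 16),
    score_day1 = jitter_col(9, 2, 17),
    score_discharge = jitter_col(4, 1.5, 18),
    los_days = jitter_col(9, 2, 19),
    cost_cny = jitter_col(20000, 4000, 20)
  )
  overrides <- list(...)
  for (nm in names(overrides)) out[[nm]] <- overrides[[nm]]
  out
}

# Minimal propensity-model stand-in with chosen logit scores.
fake_model <- function(logits, arms) {
  structure(
    list(
      coefficients = c(`(Intercept)` = 0),
      scores = plogis(logits),
      logit_scores = logits,
      id = names(logits),
      arm = arms,
      covariates = character(0),
      ridge = FALSE
    ),
    class = "propensity_model"
  )
}

# Hand-built matched dataset (bypasses the matching algorithms).
make_matched <- function(treated_id, control_id,
                         n_treated_total = length(treated_id),
                         method = "manual") {
  dvtmatch:::new_matched_dataset(method, treated_id, control_id,
                                 n_treated_total)
}

# Pair every CAV record i with SAT record i (cohort built alternating).
full_pairing <- function(cohort) {
  make_matched(cohort$id[cohort$arm == "CAV"],
               cohort$id[cohort$arm == "SAT"])
}

# Exact tail probability of the bounding signed-rank distribution:
# P(sum r_i B_i >= t) with B_i iid Bernoulli(p), by enumeration of all 2^n
# sign configurations.
exact_bound_tail <- function(d, gamma, upper = TRUE, mid = FALSE) {
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(r)
  t_obs <- sum(r[d > 0])
  p <- if (upper) gamma / (1 + gamma) else 1 / (1 + gamma)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  t_all <- drop(signs %*% r)
  k <- rowSums(signs)
  w <- p^k * (1 - p)^(n - k)
  strict <- sum(w[t_all >= t_obs - 1e-9])
  if (!mid) {
    return(strict)
  }
  # mid-tail convention: half weight on the observed atom (the quantity the
  # uncorrected normal approximation actually estimates)
  strict - 0.5 * sum(w[abs(t_all - t_obs) < 1e-9])
}

# Hodges-Lehmann point estimate: median of Walsh averages.
walsh_hl <- function(d) {
  pairs <- expand.grid(i = seq_along(d), j = seq_along(d))
  pairs <- pairs[pairs$i <= pairs$j, ]
  median((d[pairs$i] + d[pairs$j]) / 2)
}

# Greedy nearest-neighbour 1:1 matching on the line, treated visited in
# the order given; independent oracle for the optimal-vs-greedy comparison
# (the optimal total must undercut greedy under any visiting order).
greedy_total_1d <- function(tv, cv) {
  total <- 0
  avail <- rep(TRUE, length(cv))
  for (i in seq_along(tv)) {
    j <- which(avail)[which.min(abs(cv[avail] - tv[i]))]
    total <- total + abs(cv[j] - tv[i])
    avail[j] <- FALSE
  }
  total
}

# Data frame with all non-structural attributes stripped, for exact value
# comparisons that should ignore carried-along metadata.
plain_df <- function(df) {
  df <- as.data.frame(df)
  attributes(df) <- attributes(df)[c("names", "class", "row.names")]
  rownames(df) <- NULL
  df
}

# All ordered selections of m distinct controls from 1..n (rows =
# candidate assignments); brute-force oracle for tiny assignment problems.
all_assignments <- function(n, m) {
  if (m == 0) {
    return(matrix(integer(0), 1, 0))
  }
  out <- NULL
  sub <- all_assignments(n, m - 1)
  for (j in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      row <- sub[r, ]
      if (!(j %in% row)) out <- rbind(out, c(j, row))
    }
  }
  out
}

# Reduced-size pipeline configuration for end-to-end tests.
fast_config <- function(n = 396, seed = 1, ...) {
  pipeline_config(
    params = cohort_params(n_total = n, seed = seed),
    genetic_generations = 2, genetic_pop = 6,
    num_trees = 60, seed = seed, ...
  )
}
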