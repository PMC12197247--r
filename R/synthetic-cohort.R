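# Synthetic cohort generator: two-arm retrospective DVT cohorts with
# confounded treatment assignment and known injected treatment effects, so
# the matching/weighting/counterfactual machinery can be validated without
# access to hospital data.

#' Default marginal distributions for the 17 baseline covariates
#'
#' Families are skew-tolerant: truncated normals for continuous
#' anthropometrics and labs (locations at published medians, scales at
#' IQR/1.35), Bernoulli for gender (male indicator), and a discretized gamma
#' for the Wells score (rounded to 0.5 points). Lab lower bounds are
#' strictly positive.
#'
#' @return Named list of per-covariate specifications with fields `family`
#'   (`"truncnorm"`, `"bernoulli"` or `"gamma_discrete"`), `location`,
#'   `scale`, `lower`, `upper` (and `p` for Bernoulli).
#' @export
default_covariate_spec <- function() {
  tn <- function(location, scale, lower, upper = Inf) {
    list(family = "truncnorm", location = location, scale = scale,
         lower = lower, upper = upper)
  }
  list(
    age = tn(64, 17, 18, 100),
    gender = list(family = "bernoulli", p = 0.46, location = 0.46,
                  scale = sqrt(0.46 * 0.54)),
    height_cm = tn(161, 6.5, 140, 195),
    weight_kg = tn(62, 7.5, 35, 120),
    wells = list(family = "gamma_discrete", location = 4.1, scale = 0.95,
                 lower = 0, upper = 9),
    wbc = tn(9.9, 2.3, 2, 30),
    rbc = tn(5.03, 0.45, 2.5, 7.5),
    hgb = tn(15.0, 1.05, 8, 20),
    plt = tn(160, 60, 30, 600),
    hct = tn(45.5, 1.15, 30, 60),
    pt = tn(13.6, 2.1, 8, 30),
    inr = tn(1.12, 0.17, 0.6, 3),
    aptt = tn(33.0, 6.0, 15, 70),
    tt = tn(25.3, 4.4, 10, 60),
    fib = tn(3.5, 0.62, 0.8, 9),
    ddimer = tn(11.5, 5.3, 0.1, 40),
    fdp = tn(19.5, 10.0, 0.5, 80)
  )
}

#' Default propensity (treatment-assignment) coefficients
#'
#' Log-odds slopes on standardized covariates. Nonzero slopes sit on the
#' covariates that show arm imbalance in practice: combined-therapy patients
#' present with shorter APTT, lower WBC and platelet counts, longer TT, and
#' are more often male. All other covariates have zero slope. The intercept
#' `"auto"` is calibrated so the expected treated fraction matches
#' `treated_fraction`.
#'
#' @return List with `intercept` (number or `"auto"`) and named `slopes`.
#' @export
default_propensity <- function() {
  list(
    intercept = "auto",
    slopes = c(aptt = -0.8, wbc = -0.35, plt = -0.22, tt = 0.55,
               gender = 0.65)
  )
}

#' Default outcome models with injectable treatment effects
#'
#' Baseline functions are vectorized over the covariate table. The Day-1
#' symptom score depends on Wells score and D-dimer; the discharge score
#' encodes a baseline improvement fraction that falls with platelet count;
#' log-LOS rises with Wells score and age; log-cost scales with realized
#' LOS, admission severity and APTT (so economic outcomes inherit a
#' coagulation signature). Treatment shifts the discharge score by
#' `-ipr_effect_pp/100 * day1` points (an exact `ipr_effect_pp` point gain
#' in improvement rate, absent clamping), adds `los_effect_days` to LOS, and
#' multiplies cost by `exp(cost_log_ratio)`.
#'
#' @param ipr_effect_pp Injected average IPR gain, percentage points.
#' @param los_effect_days Injected additive LOS change, days.
#' @param cost_log_ratio Injected log multiplicative cost change.
#' @return List with components `day1`, `discharge`, `los`, `cost`.
#' @export
default_outcome_model <- function(ipr_effect_pp = 6.4,
                                  los_effect_days = 0.15,
                                  cost_log_ratio = -0.15) {
  list(
    day1 = list(
      baseline = function(v) {
        9 + 0.9 * (v$wells - 4.1) / 0.95 + 0.5 * (v$ddimer - 11.5) / 5.3
      },
      sd = 2.2, lower = 1
    ),
    discharge = list(
      baseline = function(v, day1) {
        day1 * (1 - (55 - 6 * (v$plt - 160) / 60) / 100)
      },
      effect = function(v, day1) -(ipr_effect_pp / 100) * day1,
      sd = 1.2
    ),
    los = list(
      log_baseline = function(v) {
        log(9) + 0.10 * (v$wells - 4.1) / 0.95 + 0.06 * (v$age - 64) / 17
      },
      effect = los_effect_days, sdlog = 0.28, lower = 0.5
    ),
    cost = list(
      log_baseline = function(v, day1, los) {
        log(21000) + 0.85 * (log(los) - log(9)) + 0.02 * (day1 - 9) +
          0.22 * (v$aptt - 33) / 6
      },
      log_effect = cost_log_ratio, sdlog = 0.30
    )
  )
}

#' Parameters for the synthetic cohort generator
#'
#' Defaults reproduce the structure of the motivating retrospective cohort:
#' 396 admissions with a 48:348 combined-therapy (CAV) to standard-therapy
#' (SAT) split, confounded assignment through coagulation parameters and
#' gender, marginals matched to published medians/IQRs, a small rate of
#' zero-improvement records that downstream exclusion rules must remove, and
#' a +6.4 percentage-point injected improvement-rate effect.
#'
#' @param n_total Number of admissions (>= 2).
#' @param treated_fraction Expected CAV share, in (0,1).
#' @param covariate_spec See [default_covariate_spec()].
#' @param propensity See [default_propensity()].
#' @param outcome_model See [default_outcome_model()]; overrides the three
#'   effect shortcuts when supplied.
#' @param ipr_effect_pp,los_effect_days,cost_log_ratio Effect shortcuts
#'   forwarded to [default_outcome_model()].
#' @param exclusion_rate Probability a record has identical Day-1 and
#'   discharge scores under both arms.
#' @param correlation Optional correlation matrix (Gaussian copula) over a
#'   subset of covariates; default independence.
#' @param seed Integer seed for the hierarchical per-record RNG streams.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_total = 396,
                          treated_fraction = 48 / 396,
                          covariate_spec = default_covariate_spec(),
                          propensity = default_propensity(),
                          outcome_model = NULL,
                          ipr_effect_pp = 6.4,
                          los_effect_days = 0.15,
                          cost_log_ratio = -0.15,
                          exclusion_rate = 7 / 403,
                          correlation = NULL,
                          seed = 1L) {
  if (is.null(outcome_model)) {
    outcome_model <- default_outcome_model(
      ipr_effect_pp = ipr_effect_pp,
      los_effect_days = los_effect_days,
      cost_log_ratio = cost_log_ratio
    )
  }
  params <- structure(
    list(
      n_total = as.integer(n_total),
      treated_fraction = treated_fraction,
      covariate_spec = covariate_spec,
      propensity = propensity,
      outcome_model = outcome_model,
      exclusion_rate = exclusion_rate,
      correlation = correlation,
      seed = as.integer(seed)
    ),
    class = "cohort_params"
  )
  validate_cohort_params(params)
  params
}

validate_cohort_params <- function(p) {
  if (p$n_total < 2) abort("n_total must be >= 2.")
  if (p$treated_fraction <= 0 || p$treated_fraction >= 1) {
    abort("treated_fraction must lie strictly inside (0, 1).")
  }
  if (p$exclusion_rate < 0 || p$exclusion_rate >= 1) {
    abort("exclusion_rate must lie in [0, 1).")
  }
  sds <- c(p$outcome_model$day1$sd, p$outcome_model$discharge$sd,
           p$outcome_model$los$sdlog, p$outcome_model$cost$sdlog)
  if (any(sds < 0)) abort("Outcome noise scales must be >= 0.")
  labs <- c("wbc", "rbc", "hgb", "plt", "hct", "pt", "inr", "aptt", "tt",
            "fib", "ddimer", "fdp")
  for (lab in intersect(labs, names(p$covariate_spec))) {
    lo <- p$covariate_spec[[lab]]$lower
    if (is.null(lo) || lo <= 0) {
      abort(paste0("Lab covariate '", lab, "' must have a positive lower bound."))
    }
  }
  unknown <- setdiff(names(p$propensity$slopes), names(p$covariate_spec))
  if (length(unknown) > 0) {
    abort(paste0("Propensity slopes on unknown covariates: ",
                 paste(unknown, collapse = ", ")))
  }
  if (!is.null(p$correlation)) {
    cm <- p$correlation
    if (is.null(rownames(cm)) ||
        !all(rownames(cm) %in% names(p$covariate_spec)) ||
        !isTRUE(all.equal(cm, t(cm)))) {
      abort("correlation must be a symmetric matrix named by covariates.")
    }
    if (any(eigen(cm, symmetric = TRUE, only.values = TRUE)$values < 1e-10)) {
      abort("correlation matrix must be positive definite.")
    }
  }
  invisible(p)
}

# ---- raw draws ------------------------------------------------------------

# One row per record: k covariate uniforms, treatment uniform, four outcome
# noise normals (day1, discharge, los, cost) and an exclusion uniform. Each
# record's row comes from its own seeded substream, so rows are invariant to
# n_total and to the presence of other records.
draw_raw <- function(params, seed, n, offset = 0) {
  k <- length(params$covariate_spec)
  out <- matrix(NA_real_, nrow = n, ncol = k + 6)
  for (i in seq_len(n)) {
    out[i, ] <- with_seed(record_seed(seed, i + offset), {
      c(runif(k), runif(1), qnorm(runif(4)), runif(1))
    })
  }
  colnames(out) <- c(names(params$covariate_spec), ".u_trt", ".n_day1",
                     ".n_dis", ".n_los", ".n_cost", ".u_excl")
  out
}

# Map covariate uniforms through the (optionally copula-correlated)
# marginals. Gender is returned as the 0/1 male indicator.
covariates_from_u <- function(params, u) {
  spec <- params$covariate_spec
  u <- u[, names(spec), drop = FALSE]
  if (!is.null(params$correlation)) {
    vars <- rownames(params$correlation)
    l <- t(chol(params$correlation))
    z <- qnorm(pmin(pmax(u[, vars, drop = FALSE], 1e-12), 1 - 1e-12))
    u[, vars] <- pnorm(z %*% t(l))
  }
  n_clamped <- sum(u < 1e-12 | u > 1 - 1e-12)
  if (n_clamped > 0) {
    inform(paste0(n_clamped, " extreme covariate draw(s) truncated to the ",
                  "support boundary."))
  }
  cols <- lapply(names(spec), function(nm) {
    s <- spec[[nm]]
    ui <- u[, nm]
    switch(s$family,
      truncnorm = q_truncnorm(ui, s$location, s$scale, s$lower, s$upper),
      bernoulli = as.numeric(ui < s$p),
      gamma_discrete = {
        shape <- (s$location / s$scale)^2
        rate <- s$location / s$scale^2
        raw <- qgamma(pmin(pmax(ui, 1e-12), 1 - 1e-12), shape = shape,
                      rate = rate)
        pmin(pmax(round(raw * 2) / 2, s$lower), s$upper)
      },
      abort(paste0("Unknown covariate family: ", s$family))
    )
  })
  names(cols) <- names(spec)
  tibble::as_tibble(cols)
}

# Standardize raw covariates by their *declared* marginal location/scale
# (not sample moments) so each record's propensity is independent of the
# rest of the cohort.
propensity_z <- function(params, cov) {
  slopes <- params$propensity$slopes
  if (length(slopes) == 0) {
    return(rep(0, nrow(cov)))
  }
  eta <- rep(0, nrow(cov))
  for (nm in names(slopes)) {
    s <- params$covariate_spec[[nm]]
    eta <- eta + slopes[[nm]] * (cov[[nm]] - s$location) / s$scale
  }
  eta
}

# Calibrate the intercept so mean assignment probability equals the target
# treated fraction. Uses a fixed internal covariate sample, so the intercept
# depends only on the parameters, never on the cohort's own draws.
propensity_intercept <- function(params) {
  a <- params$propensity$intercept
  if (is.numeric(a)) {
    return(a)
  }
  if (!identical(a, "auto")) abort("propensity intercept must be numeric or 'auto'.")
  slopes <- params$propensity$slopes
  if (length(slopes) == 0 || all(slopes == 0)) {
    return(qlogis(params$treated_fraction))
  }
  raw <- draw_raw(params, seed = 999983L, n = 4000, offset = 0)
  eta <- propensity_z(params, covariates_from_u(params, raw))
  uniroot(
    function(a0) mean(plogis(a0 + eta)) - params$treated_fraction,
    interval = c(-30, 30), tol = 1e-10
  )$root
}

eval_effect <- function(effect, ...) {
  if (is.function(effect)) effect(...) else effect
}

# Both potential-outcome arms for every record, sharing noise draws so the
# injected effects are the only systematic arm difference.
potential_outcomes <- function(params, cov, raw) {
  om <- params$outcome_model
  day1 <- pmax(om$day1$baseline(cov) + raw[, ".n_day1"] * om$day1$sd,
               om$day1$lower %||% 1)
  excl <- raw[, ".u_excl"] < params$exclusion_rate

  d_raw <- om$discharge$baseline(cov, day1) + raw[, ".n_dis"] * om$discharge$sd
  d_eff <- eval_effect(om$discharge$effect, cov, day1)
  d0 <- pmin(pmax(d_raw, 0), 1.5 * day1)
  d1 <- pmin(pmax(d_raw + d_eff, 0), 1.5 * day1)
  d0[excl] <- day1[excl]
  d1[excl] <- day1[excl]

  los_lower <- om$los$lower %||% 0.5
  los0 <- pmax(exp(om$los$log_baseline(cov) + raw[, ".n_los"] * om$los$sdlog),
               los_lower)
  los1 <- pmax(los0 + eval_effect(om$los$effect, cov), los_lower)

  cost0 <- exp(om$cost$log_baseline(cov, day1, los0) +
                 raw[, ".n_cost"] * om$cost$sdlog)
  cost1 <- exp(om$cost$log_baseline(cov, day1, los1) +
                 raw[, ".n_cost"] * om$cost$sdlog + om$cost$log_effect)

  tibble::tibble(
    score_day1 = day1,
    po_score_discharge_sat = d0, po_score_discharge_cav = d1,
    po_los_sat = los0, po_los_cav = los1,
    po_cost_sat = cost0, po_cost_cav = cost1,
    forced_zero = excl
  )
}

#' Generate a synthetic two-arm DVT cohort
#'
#' Draws `n_total` admissions from per-record seeded substreams: baseline
#' covariates from the declared marginals, treatment assignment
#' `Bernoulli(logistic(intercept + slopes . z))`, and both potential
#' outcomes per record (shared noise, additive/multiplicative injected
#' effects). The observed outcome columns equal the potential outcome of the
#' assigned arm. Bit-for-bit reproducible for a fixed seed, and adding
#' records never perturbs existing ones.
#'
#' @param params A [cohort_params()] object.
#' @param seed Integer seed; defaults to `params$seed`.
#' @return A tibble in the cohort CSV schema (see [write_cohort()]) plus
#'   potential-outcome columns (`po_*`), the true assignment probability
#'   (`ps_true`) and the zero-improvement indicator (`forced_zero`).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_params(n_total = 60, seed = 42))
#' table(cohort$arm)
generate_cohort <- function(params, seed = params$seed) {
  validate_cohort_params(params)
  raw <- draw_raw(params, seed = seed, n = params$n_total)
  cov <- covariates_from_u(params, raw)
  alpha <- propensity_intercept(params)
  ps <- plogis(alpha + propensity_z(params, cov))
  treated <- raw[, ".u_trt"] < ps
  if (all(treated) || !any(treated)) {
    active <- params$propensity$slopes[params$propensity$slopes != 0]
    abort(paste0(
      "Degenerate treatment assignment: every record landed in the ",
      if (all(treated)) "CAV" else "SAT", " arm. Check propensity ",
      "coefficients (intercept = ", signif(alpha, 4),
      if (length(active) > 0) {
        paste0("; nonzero slopes: ",
               paste(names(active), signif(active, 3), sep = "=",
                     collapse = ", "))
      } else "",
      ")."
    ))
  }
  po <- potential_outcomes(params, cov, raw)
  cohort <- dplyr::bind_cols(
    tibble::tibble(
      id = sprintf("P%05d", seq_len(params$n_total)),
      arm = ifelse(treated, "CAV", "SAT"),
      gender = ifelse(cov$gender == 1, "M", "F")
    ),
    cov[setdiff(names(cov), "gender")],
    po
  )
  cohort$score_discharge <- ifelse(treated, po$po_score_discharge_cav,
                                   po$po_score_discharge_sat)
  cohort$los_days <- ifelse(treated, po$po_los_cav, po$po_los_sat)
  cohort$cost_cny <- ifelse(treated, po$po_cost_cav, po$po_cost_sat)
  cohort$ps_true <- ps
  extra <- setdiff(names(cohort), cohort_schema())
  cohort <- cohort[, c(cohort_schema(), extra)]
  attr(cohort, "params") <- params
  attr(cohort, "seed") <- seed
  cohort
}

#' Monte-Carlo ground-truth effects on the six outcome metrics
#'
#' Draws `n_mc` covariate profiles (their own seeded substreams, disjoint
#' from any cohort's), computes both potential-outcome arms, pushes each arm
#' through the outcome-metric formulas, and averages the per-draw contrasts.
#' Draws with a zero score difference in either arm are excluded (the metric
#' ratios are undefined there) and the exclusion rate is reported. Treatment
#' assignment plays no role, so the truth is invariant to
#' `treated_fraction`.
#'
#' @param params A [cohort_params()] object.
#' @param n_mc Number of Monte-Carlo draws (>= 1e4).
#' @param seed Integer seed; defaults to `params$seed`.
#' @return Object of class `dvt_ground_truth`: list with `effects` (tibble:
#'   metric, effect, se), `n_mc`, `n_used`, `exclusion_rate`.
#' @export
ground_truth <- function(params, n_mc = 50000, seed = params$seed) {
  validate_cohort_params(params)
  if (n_mc < 1e4) abort("n_mc must be >= 1e4.")
  raw <- draw_raw(params, seed = seed, n = n_mc, offset = 10000000)
  cov <- covariates_from_u(params, raw)
  po <- potential_outcomes(params, cov, raw)
  keep <- abs(po$score_day1 - po$po_score_discharge_sat) > 0 &
    abs(po$score_day1 - po$po_score_discharge_cav) > 0
  m0 <- outcome_metric_table(po$score_day1[keep],
                             po$po_score_discharge_sat[keep],
                             po$po_los_sat[keep], po$po_cost_sat[keep])
  m1 <- outcome_metric_table(po$score_day1[keep],
                             po$po_score_discharge_cav[keep],
                             po$po_los_cav[keep], po$po_cost_cav[keep])
  diffs <- m1 - m0
  effects <- tibble::tibble(
    metric = dvt_outcomes(),
    effect = unname(colMeans(diffs)[dvt_outcomes()]),
    se = unname(apply(diffs, 2, sd)[dvt_outcomes()]) / sqrt(sum(keep))
  )
  structure(
    list(effects = effects, n_mc = n_mc, n_used = sum(keep),
         exclusion_rate = 1 - sum(keep) / n_mc),
    class = "dvt_ground_truth"
  )
}

#' @export
print.dvt_ground_truth <- function(x, ...) {
  cat("Ground-truth outcome effects (", x$n_used, "/", x$n_mc,
      " MC draws used, exclusion rate ",
      sprintf("%.3f", x$exclusion_rate), ")\n", sep = "")
  print(x$effects)
  invisible(x)
}

#' @rdname ground_truth
#' @param x A `dvt_ground_truth` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.dvt_ground_truth <- function(x, ...) {
  x$effects
}
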