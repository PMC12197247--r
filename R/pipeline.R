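# End-to-end orchestration: exclusions -> outcomes -> multi-method matching
# (triggered by the >2:1 arm-ratio rule) -> quality scoring -> ensemble
# weights -> counterfactual effects -> sensitivity sweep -> correlation
# network, with a serializable run report.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis in one validated object. Either
#' `input` (a cohort CSV path) or `params` (a [cohort_params()] simulation
#' specification) supplies the cohort.
#'
#' @param params [cohort_params()] for simulated input (used when `input`
#'   is `NULL`).
#' @param input Optional path to a cohort CSV.
#' @param covariates Matching covariates; default [dvt_covariates()].
#' @param caliper_sd Caliper width in logit-PS standard deviations.
#' @param exact_vars Exact-match variables for optimal matching.
#' @param genetic_generations,genetic_pop Genetic-search budget.
#' @param folds Cross-validation folds for predictive R^2 and the
#'   double-residual estimator.
#' @param gamma,alpha Rosenbaum robustness threshold and test level.
#' @param dim_weights Ensemble dimension weights (must sum to 1).
#' @param num_trees Trees per random forest.
#' @param dr Whether to compute double-residual estimates.
#' @param gamma_grid Sensitivity sweep grid.
#' @param network_threshold,network_method,network_scope Correlation
#'   network settings; scope `"cohort"` uses all post-exclusion records,
#'   `"matched"` the top-weighted matched sample.
#' @param seed Integer master seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(params = cohort_params(),
                            input = NULL,
                            covariates = dvt_covariates(),
                            caliper_sd = 0.2,
                            exact_vars = "gender",
                            genetic_generations = 20,
                            genetic_pop = 30,
                            folds = 5,
                            gamma = 1.5,
                            alpha = 0.05,
                            dim_weights = c(mean_smd = 0.25, max_smd = 0.15,
                                            cv_r2 = 0.25, robustness = 0.30,
                                            retention = 0.05),
                            num_trees = 500,
                            dr = TRUE,
                            gamma_grid = seq(1, 2, by = 0.1),
                            network_threshold = 0.3,
                            network_method = "spearman",
                            network_scope = c("cohort", "matched"),
                            seed = 1L) {
  config <- list(
    params = params, input = input, covariates = covariates,
    caliper_sd = caliper_sd, exact_vars = exact_vars,
    genetic_generations = genetic_generations, genetic_pop = genetic_pop,
    folds = folds, gamma = gamma, alpha = alpha,
    dim_weights = dim_weights, num_trees = num_trees, dr = dr,
    gamma_grid = gamma_grid, network_threshold = network_threshold,
    network_method = network_method,
    network_scope = match.arg(network_scope),
    seed = as.integer(seed)
  )
  if (abs(sum(config$dim_weights) - 1) > 1e-8) {
    abort("dim_weights must sum to 1.")
  }
  if (config$gamma < 1) abort("gamma must be >= 1.")
  if (config$caliper_sd <= 0) abort("caliper_sd must be positive.")
  if (config$folds < 2) abort("folds must be >= 2.")
  if (config$network_threshold <= 0 || config$network_threshold >= 1) {
    abort("network_threshold must lie in (0, 1).")
  }
  structure(config, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort input (simulation or CSV), exclusion of
#' zero-score-difference records, outcome-metric computation, multi-method
#' matching (triggered only when the arm-size ratio exceeds 2:1; otherwise
#' a single-sample analysis with a logged skip), balance and five-dimension
#' quality scoring, composite ensemble weights, counterfactual effect
#' estimation with weighted aggregation, the Rosenbaum sensitivity sweep,
#' and the correlation network. Fully reproducible from (config, seed).
#'
#' @param config A [pipeline_config()] object.
#' @return A `run_report` list; see [write_report()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  log_stage <- function(stage, ...) {
    inform(paste0("[", stage, "] ", paste0(..., collapse = "")))
  }

  cohort_raw <- if (!is.null(config$input)) {
    read_cohort(config$input)
  } else {
    generate_cohort(config$params, seed = seed)
  }
  log_stage("input", nrow(cohort_raw), " records")

  excl <- apply_exclusions(cohort_raw)
  cohort <- compute_outcomes(excl$cohort)
  log_stage("exclusions", nrow(excl$log), " excluded, ",
            nrow(cohort), " retained")

  n_cav <- sum(cohort$arm == "CAV")
  n_sat <- sum(cohort$arm == "SAT")
  ratio <- max(n_sat, n_cav) / min(n_sat, n_cav)
  multi <- ratio > 2
  covs <- config$covariates

  if (multi) {
    log_stage("matching", "arm ratio ", sprintf("%.2f", ratio),
              " > 2: running four matching methods")
    model <- fit_propensity(cohort, covs)
    matched <- list(
      genetic = match_genetic(
        cohort, covs, generations = config$genetic_generations,
        pop_size = config$genetic_pop, seed = seed
      ),
      mahalanobis = match_mahalanobis(cohort, covs),
      nearest_caliper = match_nearest_caliper(model, config$caliper_sd),
      optimal_exact = match_optimal_exact(model, cohort, config$exact_vars)
    )
    balance <- purrr::map(matched, balance_report, data = cohort,
                          covariates = covs)
    quality <- method_quality(
      matched, cohort, covariates = covs, k = config$folds,
      gamma = config$gamma, alpha = config$alpha, seed = seed,
      num_trees = config$num_trees
    )
    weights <- composite_weight(quality, dim_weights = config$dim_weights)
    log_stage("weights", paste(weights$method,
                               sprintf("%.3f", weights$weight),
                               sep = "=", collapse = ", "))
    effects <- effect_table(
      matched, cohort, weights, covariates = covs, seed = seed,
      num_trees = config$num_trees, k = config$folds, dr = config$dr
    )
    sensitivity <- purrr::map_dfr(matched, function(m) {
      dplyr::mutate(
        sensitivity_sweep(m, cohort, gamma_grid = config$gamma_grid),
        method = m$method, .before = 1
      )
    })
    importance <- purrr::map_dfr(dvt_outcomes(), function(oc) {
      per <- purrr::map(matched, variable_importance, data = cohort,
                       outcome = oc, covariates = covs, seed = seed,
                       num_trees = config$num_trees)
      w <- setNames(weights$weight, weights$method)
      agg <- Reduce(`+`, purrr::imap(per, function(tb, m) {
        w[[m]] * tb$importance
      }))
      tibble::tibble(outcome = oc, covariate = per[[1]]$covariate,
                     importance = agg)
    })
  } else {
    log_stage("matching", "arm ratio ", sprintf("%.2f", ratio),
              " <= 2: matching skipped, single-sample analysis")
    model <- NULL
    matched <- NULL
    balance <- NULL
    quality <- NULL
    weights <- NULL
    effects <- effect_table(
      list(unmatched = NULL), cohort, weights = NULL, covariates = covs,
      seed = seed, num_trees = config$num_trees, k = config$folds,
      dr = config$dr
    )
    sensitivity <- NULL
    importance <- purrr::map_dfr(dvt_outcomes(), function(oc) {
      dplyr::mutate(
        variable_importance(NULL, cohort, oc, covs, seed = seed,
                            num_trees = config$num_trees),
        outcome = oc, .before = 1
      )
    })
  }
  log_stage("effects", nrow(effects), " effect rows")

  net_data <- if (config$network_scope == "matched" && multi) {
    top <- weights$method[which.max(weights$weight)]
    cohort[match(matched_ids(matched[[top]]), cohort$id), , drop = FALSE]
  } else {
    cohort
  }
  network <- build_network(
    correlation_matrix(net_data, method = config$network_method),
    threshold = config$network_threshold,
    importance = importance
  )
  log_stage("network", nrow(network$edges), " edges")

  structure(
    list(
      cohort = cohort,
      exclusions = excl$log,
      arm_ratio = ratio,
      matching_performed = multi,
      propensity = model,
      matched = matched,
      balance = balance,
      quality = quality,
      weights = weights,
      effects = effects,
      sensitivity = sensitivity,
      importance = importance,
      network = network,
      provenance = list(
        seed = seed,
        config_hash = rlang::hash(config),
        package_version = as.character(utils::packageVersion("dvtmatch")),
        r_version = paste(R.version$major, R.version$minor, sep = ".")
      )
    ),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("dvtmatch run report (seed ", x$provenance$seed, ")\n", sep = "")
  cat("  cohort: ", nrow(x$cohort), " records (",
      nrow(x$exclusions), " excluded); arm ratio ",
      sprintf("%.2f", x$arm_ratio), "\n", sep = "")
  if (x$matching_performed) {
    cat("  weights: ", paste(x$weights$method,
                             sprintf("%.3f", x$weights$weight),
                             sep = "=", collapse = ", "), "\n", sep = "")
  } else {
    cat("  matching skipped (arm ratio <= 2)\n")
  }
  cat("  effects table: ", nrow(x$effects), " rows\n", sep = "")
  invisible(x)
}

#' Write a run report to disk
#'
#' Serializes every stage artifact as plain text: cohort and per-stage
#' CSVs, ensemble weights and provenance as JSON, and the network as
#' GraphML. Identical (config, seed) pairs produce byte-identical files.
#'
#' @param report A [run_pipeline()] report.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put_csv <- function(obj, name) {
    p <- file.path(dir, name)
    readr::write_csv(obj, p, progress = FALSE)
    paths[[name]] <<- p
  }
  put_csv(report$cohort, "cohort.csv")
  put_csv(report$exclusions, "exclusions.csv")
  put_csv(report$effects, "effects.csv")
  put_csv(report$importance, "importance.csv")
  put_csv(report$network$nodes, "network_nodes.csv")
  put_csv(report$network$edges, "network_edges.csv")
  if (report$matching_performed) {
    put_csv(
      purrr::imap_dfr(report$balance, function(b, m) {
        dplyr::mutate(tibble::as_tibble(b), method = m, .before = 1)
      }),
      "balance.csv"
    )
    put_csv(
      purrr::imap_dfr(report$matched, function(m, nm) {
        dplyr::mutate(m$pairs, method = nm, .before = 1)
      }),
      "pairs.csv"
    )
    put_csv(report$quality, "quality.csv")
    put_csv(report$sensitivity, "sensitivity.csv")
    p <- file.path(dir, "weights.json")
    jsonlite::write_json(
      setNames(as.list(report$weights$weight), report$weights$method),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    paths[["weights.json"]] <- p
  }
  p <- file.path(dir, "network.graphml")
  write_graphml(report$network, p)
  paths[["network.graphml"]] <- p
  p <- file.path(dir, "provenance.json")
  jsonlite::write_json(report$provenance, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths[["provenance.json"]] <- p
  invisible(paths)
}
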