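# Thresholded correlation network linking baseline covariates and outcome
# metrics, with importance-scaled nodes and GraphML export.

#' Correlation matrix over baseline and outcome variables
#'
#' Spearman by default (labs and ratio-type outcomes are skewed); Pearson
#' available. Gender is coded as the 0/1 male indicator. A constant
#' variable gets zero correlations (undefined-as-0) with a warning.
#'
#' @param data Cohort tibble (at least 3 complete records).
#' @param variables Variable names; default baseline covariates plus the
#'   six outcome metrics.
#' @param method `"spearman"` or `"pearson"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(data,
                               variables = c(dvt_covariates(),
                                             dvt_outcomes()),
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  assert_cohort_columns(data, variables)
  x <- as.data.frame(data[variables])
  if ("gender" %in% variables) x$gender <- gender_indicator(x$gender)
  x <- as.matrix(x)
  if (nrow(x) < 3 || any(!complete.cases(x))) {
    abort("Need at least 3 complete records with numeric variables.")
  }
  constant <- apply(x, 2, function(col) sd(col) < 1e-12)
  m <- suppressWarnings(cor(x, method = method))
  if (any(constant)) {
    warn(paste0("Constant variable(s) with undefined correlations set to 0: ",
                paste(colnames(x)[constant], collapse = ", ")))
    m[constant, ] <- 0
    m[, constant] <- 0
  }
  diag(m) <- 1
  m
}

#' Build the thresholded correlation network
#'
#' Keeps an edge for every unordered variable pair with `|r|` strictly
#' greater than the threshold (default 0.3). Nodes are classed as baseline
#' or outcome; edges as baseline-baseline, baseline-outcome or
#' outcome-outcome. Baseline node importance is the summed normalized
#' variable importance across outcomes when an importance table is
#' supplied, otherwise the node degree; outcome node importance is the
#' degree.
#'
#' @param matrix Correlation matrix from [correlation_matrix()].
#' @param threshold Absolute-correlation threshold in (0, 1).
#' @param importance Optional tibble (`outcome`, `covariate`, `importance`)
#'   as stacked [variable_importance()] results.
#' @param outcome_vars Names treated as outcome nodes; default
#'   [dvt_outcomes()].
#' @return A `correlation_network`: list with `nodes` (node, class,
#'   importance), `edges` (var_a, var_b, r, edge_class) and `threshold`.
#' @export
build_network <- function(matrix, threshold = 0.3, importance = NULL,
                          outcome_vars = dvt_outcomes()) {
  if (threshold <= 0 || threshold >= 1) {
    abort("threshold must lie strictly inside (0, 1).")
  }
  vars <- colnames(matrix)
  cls <- ifelse(vars %in% outcome_vars, "outcome", "baseline")
  idx <- which(upper.tri(matrix) & abs(matrix) > threshold, arr.ind = TRUE)
  edges <- tibble::tibble(
    var_a = vars[idx[, 1]],
    var_b = vars[idx[, 2]],
    r = matrix[idx]
  )
  class_of <- setNames(cls, vars)
  edges$edge_class <- paste(
    pmin(class_of[edges$var_a], class_of[edges$var_b]),
    pmax(class_of[edges$var_a], class_of[edges$var_b]),
    sep = "-"
  )
  edges <- edges[order(edges$var_a, edges$var_b), , drop = FALSE]

  degree <- vapply(vars, function(v) {
    sum(edges$var_a == v | edges$var_b == v)
  }, numeric(1))
  node_importance <- degree
  if (!is.null(importance)) {
    agg <- tapply(importance$importance, importance$covariate, sum)
    base <- vars[cls == "baseline"]
    node_importance[base] <- as.numeric(agg[base])
    node_importance[is.na(node_importance)] <- 0
  }
  structure(
    list(
      nodes = tibble::tibble(node = vars, class = cls,
                             importance = unname(node_importance)),
      edges = edges,
      threshold = threshold
    ),
    class = "correlation_network"
  )
}

#' @export
print.correlation_network <- function(x, ...) {
  cat("Correlation network: ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (|r| > ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' @rdname build_network
#' @param x A `correlation_network`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.correlation_network <- function(x, ...) {
  x$edges
}

#' @rdname build_network
#' @exportS3Method generics::glance
#' @export
glance.correlation_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    threshold = x$threshold,
    n_baseline_outcome = sum(x$edges$edge_class == "baseline-outcome")
  )
}

#' Convert a correlation network to an igraph object
#'
#' @param network A `correlation_network`.
#' @return An undirected `igraph` graph with `class`/`importance` node
#'   attributes and `r`/`edge_class` edge attributes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "correlation_network"))
  igraph::graph_from_data_frame(
    d = as.data.frame(network$edges),
    directed = FALSE,
    vertices = as.data.frame(network$nodes)
  )
}

#' Write a correlation network as GraphML
#'
#' @param network A `correlation_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), file = path, format = "graphml")
  invisible(path)
}
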