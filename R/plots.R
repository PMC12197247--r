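# ggplot2 visual summaries: love plot for balance, weight decomposition,
# ITE densities, sensitivity curves and the correlation network.

#' Love plot of covariate balance before/after matching
#'
#' @param balance A `balance_table` or a named list of them (one per
#'   method).
#' @param ref_lines SMD reference lines (default 0.1 and 0.3).
#' @return A ggplot object.
#' @export
plot_balance <- function(balance, ref_lines = c(0.1, 0.3)) {
  if (inherits(balance, "balance_table")) {
    balance <- list(balance)
    names(balance) <- attr(balance[[1]], "method") %||% "matched"
  }
  df <- purrr::imap_dfr(balance, function(b, m) {
    dplyr::mutate(tibble::as_tibble(b), method = m)
  })
  long <- tidyr::pivot_longer(df, c("smd_before", "smd_after"),
                              names_to = "stage", values_to = "smd")
  long$stage <- factor(long$stage, levels = c("smd_before", "smd_after"),
                       labels = c("before", "after"))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$smd, y = .data$covariate, colour = .data$stage
  )) +
    ggplot2::geom_vline(xintercept = ref_lines, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "absolute standardized mean difference", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_balance
#' @param object A `balance_table`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.balance_table <- function(object, ...) {
  plot_balance(object)
}

#' Bar chart of ensemble weights with their dimension shares
#'
#' @param weights An `ensemble_weights` object.
#' @return A ggplot object.
#' @export
plot_weights <- function(weights) {
  stopifnot(inherits(weights, "ensemble_weights"))
  shares <- attr(weights, "shares")
  dimw <- attr(weights, "dim_weights")
  contrib <- sweep(shares[, names(dimw), drop = FALSE], 2, dimw, "*")
  df <- tibble::as_tibble(contrib)
  df$method <- rownames(shares)
  long <- tidyr::pivot_longer(df, -"method", names_to = "dimension",
                              values_to = "contribution")
  ggplot2::ggplot(long, ggplot2::aes(
    x = stats::reorder(.data$method, .data$contribution, sum),
    y = .data$contribution, fill = .data$dimension
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "composite weight contribution",
                  fill = "dimension") +
    ggplot2::theme_minimal()
}

#' @rdname plot_weights
#' @param object An `ensemble_weights` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ensemble_weights <- function(object, ...) {
  plot_weights(object)
}

#' Density plot of individual treatment effects by arm
#'
#' @param ite An `ite_vector` from [t_learner()].
#' @return A ggplot object.
#' @export
plot_ite <- function(ite) {
  stopifnot(inherits(ite, "ite_vector"))
  ggplot2::ggplot(ite, ggplot2::aes(x = .data$ite, fill = .data$arm)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = mean(ite$ite), linetype = "dashed") +
    ggplot2::labs(
      x = paste0("individual treatment effect (",
                 attr(ite, "outcome") %||% "outcome", ")"),
      y = "density", fill = NULL,
      title = attr(ite, "method") %||% NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_ite
#' @param object An `ite_vector`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ite_vector <- function(object, ...) {
  plot_ite(object)
}

#' Sensitivity curves: p-value bounds across gamma
#'
#' @param curves A `sensitivity_curve` tibble (optionally with a `method`
#'   column).
#' @param alpha Significance reference line.
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(curves, alpha = 0.05) {
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$gamma))
  if ("method" %in% names(curves)) {
    p <- p +
      ggplot2::geom_ribbon(
        ggplot2::aes(ymin = .data$p_lower, ymax = .data$p_upper,
                     fill = .data$method), alpha = 0.2
      ) +
      ggplot2::geom_line(ggplot2::aes(y = .data$p_upper,
                                      colour = .data$method))
  } else {
    p <- p +
      ggplot2::geom_ribbon(
        ggplot2::aes(ymin = .data$p_lower, ymax = .data$p_upper),
        alpha = 0.2
      ) +
      ggplot2::geom_line(ggplot2::aes(y = .data$p_upper))
  }
  p +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::labs(x = expression(Gamma), y = "p-value bounds") +
    ggplot2::theme_minimal()
}

#' @rdname plot_sensitivity
#' @param object A `sensitivity_curve`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.sensitivity_curve <- function(object, ...) {
  plot_sensitivity(object)
}

#' Correlation network plot with importance-scaled nodes
#'
#' @param network A `correlation_network`.
#' @param seed Layout seed (Fruchterman-Reingold).
#' @return A ggplot object.
#' @export
plot_network <- function(network, seed = 1L) {
  stopifnot(inherits(network, "correlation_network"))
  g <- as_igraph(network)
  layout <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- network$nodes[match(igraph::V(g)$name, network$nodes$node), ]
  nodes$x <- layout[, 1]
  nodes$y <- layout[, 2]
  pos <- setNames(seq_len(nrow(nodes)), nodes$node)
  edges <- network$edges
  edges$x <- nodes$x[pos[edges$var_a]]
  edges$y <- nodes$y[pos[edges$var_a]]
  edges$xend <- nodes$x[pos[edges$var_b]]
  edges$yend <- nodes$y[pos[edges$var_b]]
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = abs(.data$r),
                   colour = .data$edge_class),
      alpha = 0.6
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$importance,
                   shape = .data$class)
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
      vjust = -1, size = 3
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::labs(colour = "edge", shape = "node", size = "importance") +
    ggplot2::theme_void()
}

#' @rdname plot_network
#' @param object A `correlation_network`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.correlation_network <- function(object, ...) {
  plot_network(object)
}
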