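#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# rectangular tree layout: x = depth from root (Myr when lengths exist,
# node rank otherwise), y = tip order
tree_layout <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_nodes <- n_tip + tree$Nnode
  len <- tree$edge.length %||% rep(1, nrow(tree$edge))
  depth <- numeric(n_nodes)
  pre <- reorder(tree, "cladewise")$edge
  pre_len <- if (is.null(tree$edge.length)) rep(1, nrow(pre)) else
    reorder(tree, "cladewise")$edge.length
  for (i in seq_len(nrow(pre))) {
    depth[pre[i, 2]] <- depth[pre[i, 1]] + pre_len[i]
  }
  yy <- numeric(n_nodes)
  yy[seq_len(n_tip)] <- seq_len(n_tip)
  po <- postorder_edges(tree)
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1]
    kids <- po[po[, 1] == p, 2]
    yy[p] <- mean(yy[kids])
  }
  tibble(node = seq_len(n_nodes), x = depth, y = yy, label = node_ids(tree))
}

#' Plot a parsimony reconstruction on the tree
#'
#' Draws the tree with branches and nodes coloured by reconstructed
#' linkage state; change branches carry the inferred events.
#'
#' @param object A `y_reconstruction`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.y_reconstruction <- function(object, ...) {
  tree <- object$tree
  lay <- tree_layout(tree)
  ed <- tree$edge
  seg <- tibble(
    x = lay$x[ed[, 1]], xend = lay$x[ed[, 2]],
    y = lay$y[ed[, 2]], yend = lay$y[ed[, 2]],
    state = unname(object$node_state[ed[, 2]])
  )
  vert <- tibble(
    x = lay$x[ed[, 1]], xend = lay$x[ed[, 1]],
    y = lay$y[ed[, 1]], yend = lay$y[ed[, 2]],
    state = unname(object$node_state[ed[, 1]])
  )
  tips <- lay[lay$node <= ape::Ntip(tree), ]
  pal <- c(Y = "#1b7837", AX = "#2166ac", absent = "#b2182b")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = bind_rows(seg, vert),
      ggplot2::aes(x = x, xend = xend, y = y, yend = yend, colour = state),
      linewidth = 0.7
    ) +
    ggplot2::geom_text(
      data = tips,
      ggplot2::aes(x = x, y = y, label = label),
      hjust = -0.1, size = 3
    ) +
    ggplot2::scale_colour_manual(values = pal, name = "state") +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0.02, 0.15))) +
    ggplot2::labs(
      title = sprintf("%s: %d change(s), min cost %g",
        object$gene, nrow(object$changes), object$min_cost),
      x = if (has_branch_lengths(tree)) "depth (Myr)" else "depth (node rank)",
      y = NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      panel.grid.major.y = ggplot2::element_blank(),
      panel.grid.minor = ggplot2::element_blank()
    )
}

#' Plot a rate estimate with its exact confidence interval
#'
#' @param object A `y_rate_estimate`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.y_rate_estimate <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = method, y = estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = conf.low, ymax = conf.high)) +
    ggplot2::labs(
      y = "events per unit exposure",
      x = NULL,
      title = sprintf(
        "%d events / %g exposure (%g%% CI)",
        object$n_events, object$exposure, 100 * object$conf
      )
    ) +
    ggplot2::theme_minimal()
}

#' Heat-map of a linkage matrix
#'
#' Species by gene tile plot of the PCR observation states.
#'
#' @param matrix A `linkage_matrix`.
#' @return A ggplot.
#' @export
plot_linkage_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "linkage_matrix"))
  long <- linkage_long(matrix)
  long$state <- factor(long$state, levels = c("M", "MF", "F"))
  pal <- c(M = "#1b7837", MF = "#2166ac", F = "#b2182b")
  ggplot2::ggplot(long, ggplot2::aes(x = gene, y = species, fill = state)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = pal, na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot recovery-experiment replicate intervals
#'
#' Replicate CIs against the true simulated rate (horizontal line);
#' intervals missing the truth are highlighted.
#'
#' @param object A `y_recovery`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.y_recovery <- function(object, ...) {
  r <- object$replicates
  ggplot2::ggplot(r, ggplot2::aes(x = replicate, y = rate, colour = covered)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = ci_low, ymax = ci_high), linewidth = 0.3, size = 0.2
    ) +
    ggplot2::geom_hline(yintercept = object$lambda_transfer, linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "grey40", `FALSE` = "#b2182b"), name = "CI covers truth"
    ) +
    ggplot2::labs(
      x = "replicate", y = "estimated rate (/gene/Myr)",
      title = sprintf("Garwood %g%% CI recovery of lambda = %g",
        100 * object$conf, object$lambda_transfer)
    ) +
    ggplot2::theme_minimal()
}
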