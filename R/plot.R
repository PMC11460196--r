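#' Plot a fitted PALM tree
#'
#' A node-link diagram: internal nodes labelled with the split variable
#' and adjusted p-value, leaves with the subgroup size and the slope of
#' distress per unit decrease in support.
#'
#' @param object A `"palm_tree"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot palm_tree
#' @export
autoplot.palm_tree <- function(object, ...) {
  tree <- object$tree
  nodes <- list()
  edges <- list()
  layout <- function(node, depth, xmin, xmax) {
    xc <- (xmin + xmax) / 2
    lab <- if (is.null(node$kids)) {
      sprintf("n = %d\nslope = %.2f", node$n, node$coef[2])
    } else {
      p <- node$split$p_adj
      sprintf("%s\n%s", node$split$variable,
              if (p < 0.001) "p < 0.001" else sprintf("p = %.3g", p))
    }
    nodes[[length(nodes) + 1]] <<- tibble::tibble(
      id = node$id, x = xc, y = -depth, label = lab,
      leaf = is.null(node$kids))
    if (!is.null(node$kids)) {
      mids <- c(xmin, xc, xmax)
      for (i in 1:2) {
        kid <- node$kids[[i]]
        kx <- (mids[i] + mids[i + 1]) / 2
        edges[[length(edges) + 1]] <<- tibble::tibble(
          x = xc, y = -depth, xend = kx, yend = -(depth + 1),
          label = describe_condition(node$split, i == 1))
        layout(kid, depth + 1, mids[i], mids[i + 1])
      }
    }
  }
  layout(tree$root, 1, 0, 1)
  nd <- dplyr::bind_rows(nodes)
  ed <- dplyr::bind_rows(edges)
  p <- ggplot2::ggplot()
  if (nrow(ed)) {
    p <- p +
      ggplot2::geom_segment(data = ed, ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
        colour = "grey50") +
      ggplot2::geom_label(data = ed, ggplot2::aes(
        x = (.data$x + .data$xend) / 2, y = (.data$y + .data$yend) / 2,
        label = .data$label), size = 2.6, colour = "grey30")
  }
  p +
    ggplot2::geom_label(data = nd, ggplot2::aes(
      x = .data$x, y = .data$y, label = .data$label, fill = .data$leaf),
      size = 3, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#d9ead3",
                                          `FALSE` = "#cfe2f3")) +
    ggplot2::theme_void()
}

#' Forest-style plot of the subgroup estimates
#'
#' @param analysis A [run_analysis()] result (or a tidy subgroup table).
#' @return A ggplot object: per-outcome subgroup slopes with 95%
#'   confidence intervals.
#' @export
plot_subgroups <- function(analysis) {
  tab <- if (inherits(analysis, "palm_analysis")) analysis$table else analysis
  ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$estimate, y = .data$subgroup)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$conf.low, xmax = .data$conf.high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(~ outcome, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "z-score change per unit decrease in SSQN",
                  y = NULL) +
    ggplot2::theme_minimal()
}
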