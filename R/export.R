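#' Serialize a fitted tree to JSON
#'
#' Nodes carry ids, sizes, coefficients, the per-variable instability
#' results and the chosen split; for a PALM fit the global coefficients
#' and convergence trace are embedded alongside.
#'
#' @param model A `"mob_tree"` or `"palm_tree"`.
#' @param path Optional file path; when given, the JSON is written there.
#' @return The JSON string, invisibly when written to a file.
#' @export
tree_json <- function(model, path = NULL) {
  to_list <- function(node) {
    out <- list(id = node$id, depth = node$depth, n = node$n,
                coef = as.list(node$coef), rss = node$rss)
    if (!is.null(node$tests)) {
      out$instability <- lapply(seq_len(nrow(node$tests)), function(i)
        as.list(node$tests[i, ]))
    }
    if (!is.null(node$split)) {
      out$split <- node$split[setdiff(names(node$split), "objective")]
      out$children <- list(to_list(node$kids[[1]]), to_list(node$kids[[2]]))
    }
    out
  }
  if (inherits(model, "palm_tree")) {
    payload <- list(type = "palm_tree",
                    gamma = as.list(model$gamma),
                    dropped_globals = model$dropped_globals,
                    objective_trace = model$objective_trace,
                    converged = model$converged,
                    leaf_estimates = model$leaf_estimates,
                    tree = to_list(model$tree$root))
  } else {
    stopifnot(inherits(model, "mob_tree"))
    payload <- list(type = "mob_tree", tree = to_list(model$root))
  }
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Graphviz DOT export of a fitted tree
#'
#' Internal nodes show the split variable and its (adjusted) p-value,
#' leaves the subgroup size and slope estimate — mirroring the layout of
#' published MOB tree figures.
#'
#' @param model A `"mob_tree"` or `"palm_tree"`.
#' @param path Optional file path.
#' @return The DOT source as a character scalar.
#' @export
tree_dot <- function(model, path = NULL) {
  tree <- if (inherits(model, "palm_tree")) model$tree else model
  stopifnot(inherits(tree, "mob_tree"))
  lines <- c("digraph mob_tree {", "  node [shape=box, fontsize=10];")
  walk <- function(node) {
    if (is.null(node$kids)) {
      lines <<- c(lines, sprintf(
        "  n%d [label=\"n = %d\\nslope = %.2f\"];",
        node$id, node$n, node$coef[2]))
    } else {
      p <- node$split$p_adj
      plab <- if (p < 0.001) "p < 0.001" else sprintf("p = %.3g", p)
      lines <<- c(lines, sprintf("  n%d [label=\"%s\\n%s\"];",
                                 node$id, node$split$variable, plab))
      for (i in 1:2) {
        kid <- node$kids[[i]]
        lines <<- c(lines, sprintf("  n%d -> n%d [label=\"%s\"];",
                                   node$id, kid$id,
                                   gsub("\"", "'", describe_condition(
                                     node$split, i == 1))))
        walk(kid)
      }
    }
  }
  walk(tree$root)
  lines <- c(lines, "}")
  src <- paste(lines, collapse = "\n")
  if (!is.null(path)) writeLines(src, path)
  src
}
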