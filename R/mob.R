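#' Control parameters for model-based recursive partitioning
#'
#' @param alpha Significance level for the (adjusted) instability test; a
#'   node splits only if the smallest adjusted p-value is `<= alpha`.
#'   `alpha = 1` always splits where admissible, so tree size is governed
#'   by `maxdepth` alone — the exploratory setting used for the cohort
#'   analysis.
#' @param maxdepth Maximum tree depth; the root has depth 1, so
#'   `maxdepth = 3` allows at most two nested splits (four leaves).
#' @param minsize Minimum number of observations per child node.
#' @param bonferroni Multiply raw p-values by the number of tested
#'   modifiers (capped at 1)?
#' @param trim Boundary trimming fraction for the supLM statistic of
#'   ordered modifiers.
#' @param n_mc Monte-Carlo replicates for the supLM p-value.
#' @param seed Seed for the Monte-Carlo p-value simulation.
#' @return A list of class `"mob_control"`.
#' @export
mob_control <- function(alpha = 1, maxdepth = 3L, minsize = 20L,
                        bonferroni = TRUE, trim = 0.1, n_mc = 10000L,
                        seed = 1L) {
  stopifnot(alpha > 0, alpha <= 1, maxdepth >= 1, minsize >= 2,
            trim > 0, trim < 0.5, n_mc >= 100)
  structure(list(alpha = alpha, maxdepth = as.integer(maxdepth),
                 minsize = as.integer(minsize), bonferroni = bonferroni,
                 trim = trim, n_mc = as.integer(n_mc),
                 seed = as.integer(seed)),
            class = "mob_control")
}

#' Fit the node model (simple linear regression with scores)
#'
#' Ordinary least squares of `y` on an intercept and `x`, returning the
#' coefficients, residual sum of squares and the per-observation
#' estimating functions `psi_i = (r_i, r_i * x_i)` whose fluctuation the
#' instability tests examine.
#'
#' @param y,x Numeric vectors.
#' @return List of class `"node_model"` with `theta`, `rss`,
#'   `score_rows`, `n`.
#' @export
fit_node_model <- function(y, x) {
  n <- length(y)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (length(x) != n || anyNA(x) || anyNA(y)) {
    stop("y and x must be complete and of equal length", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("degenerate regressor: x is constant", call. = FALSE)
  fit <- stats::.lm.fit(cbind(1, x), y)
  r <- fit$residuals
  structure(list(theta = stats::setNames(fit$coefficients[1:2],
                                         c("intercept", "slope")),
                 rss = sum(r^2),
                 score_rows = cbind(r, r * x),
                 n = n),
            class = "node_model")
}

#' Parameter instability test for a categorical modifier
#'
#' Sums the estimating functions within each level of `z` and forms the
#' chi-square fluctuation statistic
#' `T = sum_c S_c' Vhat^{-1} S_c / n_c` with
#' `Vhat = crossprod(psi) / n`; under parameter stability `T` is
#' asymptotically chi-square with `k * (C - 1)` degrees of freedom
#' (k = 2 model parameters, C levels).
#'
#' @param model A [fit_node_model()] result.
#' @param z Factor (or vector coercible to one) with at least 2 observed
#'   levels, same length as the node data.
#' @return Tibble row: `statistic`, `df`, `p_raw`.
#' @export
instability_test_categorical <- function(model, z) {
  psi <- model$score_rows
  z <- factor(z)
  z <- droplevels(z)
  n <- model$n
  if (length(z) != n) stop("modifier length mismatch", call. = FALSE)
  C <- nlevels(z)
  if (C < 2) stop("modifier has fewer than 2 observed levels", call. = FALSE)
  V <- crossprod(psi) / n
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vi)) stop("singular score covariance; node unsplittable on this variable",
                        call. = FALSE)
  S <- rowsum(psi, z)                      # C x 2 level sums
  n_c <- as.vector(table(z))
  stat <- sum(vapply(seq_len(C), function(c)
    drop(S[c, ] %*% Vi %*% S[c, ]) / n_c[c], numeric(1)))
  df <- 2 * (C - 1)
  tibble::tibble(statistic = stat, df = df,
                 p_raw = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Parameter instability test for an ordered or numeric modifier
#'
#' Orders the observations by `z`, forms the decorrelated cumulative
#' score process and takes the supLM functional
#' `max_t ||W(t)||^2 / (t (1 - t))` over the observed split fractions
#' inside `[trim, 1 - trim]`. The p-value is obtained by seeded Monte
#' Carlo: the null process is a 2-dimensional Brownian bridge evaluated
#' on the same grid.
#'
#' @param model A [fit_node_model()] result.
#' @param z Ordered or numeric vector.
#' @param trim Boundary trimming fraction.
#' @param n_mc Monte-Carlo replicates.
#' @param seed Seed for the Monte-Carlo simulation.
#' @return Tibble row: `statistic`, `n_mc`, `p_raw`.
#' @export
instability_test_ordered <- function(model, z, trim = 0.1, n_mc = 10000L,
                                     seed = 1L) {
  psi <- model$score_rows
  n <- model$n
  if (length(z) != n) stop("modifier length mismatch", call. = FALSE)
  if (length(unique(z)) < 2) stop("modifier has fewer than 2 distinct values",
                                  call. = FALSE)
  if (max(abs(psi)) < 1e-12) {      # exact fit: no fluctuation to test
    return(tibble::tibble(statistic = 0, n_mc = as.integer(n_mc), p_raw = 1))
  }
  V <- crossprod(psi) / n
  e <- eigen(V, symmetric = TRUE)
  if (min(e$values) <= 1e-12 * max(e$values)) {
    stop("singular score covariance; node unsplittable on this variable",
         call. = FALSE)
  }
  Vih <- e$vectors %*% diag(1 / sqrt(e$values), 2) %*% t(e$vectors)
  ord <- order(z)
  cs <- apply(psi[ord, , drop = FALSE] %*% Vih, 2, cumsum) / sqrt(n)
  z_sorted <- z[ord]
  # admissible split fractions: ends of tie groups, inside the trim band
  grid_idx <- which(z_sorted != c(z_sorted[-1], NA))
  t_grid <- grid_idx / n
  keep <- t_grid >= trim & t_grid <= 1 - trim
  if (!any(keep)) stop("no admissible split fractions after trimming", call. = FALSE)
  grid_idx <- grid_idx[keep]
  t_grid <- t_grid[keep]
  wsq <- rowSums(cs[grid_idx, , drop = FALSE]^2)
  stat <- max(wsq / (t_grid * (1 - t_grid)))
  p_raw <- suplm_mc_pvalue(stat, t_grid, n_mc = n_mc, seed = seed)
  tibble::tibble(statistic = stat, n_mc = as.integer(n_mc), p_raw = p_raw)
}

# Null distribution of the supLM functional on a fixed fraction grid:
# simulate 2-dim Brownian bridges via scaled Gaussian increments.
suplm_mc_pvalue <- function(stat, t_grid, n_mc, seed, k = 2L) {
  g <- length(t_grid)
  dt <- diff(c(0, t_grid, 1))
  scale <- t_grid * (1 - t_grid)
  chunk <- max(1L, min(n_mc, as.integer(2e6 / (g + 1))))
  null_max <- withr_seed(seed, {
    vals <- numeric(0)
    left <- n_mc
    while (left > 0) {
      b <- min(chunk, left)
      bb_sq <- matrix(0, g, b)
      for (j in seq_len(k)) {
        incr <- matrix(stats::rnorm((g + 1) * b), g + 1, b) * sqrt(dt)
        w <- apply(incr, 2, cumsum)
        bb <- w[seq_len(g), , drop = FALSE] -
          tcrossprod(t_grid, w[g + 1, ])
        bb_sq <- bb_sq + bb^2
      }
      vals <- c(vals, apply(bb_sq / scale, 2, max))
      left <- left - b
    }
    vals
  })
  mean(null_max >= stat)
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Select the splitting variable from instability results
#'
#' Applies the Bonferroni adjustment `p_adj = min(1, m * p_raw)` over the
#' `m` tested modifiers, picks the variable with the smallest adjusted
#' p-value (ties broken by larger statistic, then smaller index) and
#' returns `NULL` if the minimum exceeds `alpha`.
#'
#' @param results Tibble with columns `variable`, `statistic`, `p_raw`.
#' @param control A [mob_control()].
#' @return List with `variable`, `p_adj`, or `NULL` when no split.
#' @export
select_variable <- function(results, control = mob_control()) {
  stopifnot(nrow(results) >= 1)
  m <- nrow(results)
  p_adj <- if (control$bonferroni) pmin(1, m * results$p_raw) else results$p_raw
  ord <- order(p_adj, -results$statistic, seq_len(m))
  best <- ord[1]
  if (p_adj[best] > control$alpha) return(NULL)
  list(variable = results$variable[best], p_adj = p_adj[best],
       p_raw = results$p_raw[best], statistic = results$statistic[best])
}

#' Exhaustive split search on the selected variable
#'
#' Categorical `z`: evaluates all `2^(C-1) - 1` binary partitions of the
#' observed levels; ordered/numeric `z`: all midpoints between
#' consecutive distinct values. The objective is the summed residual sum
#' of squares of the two child OLS fits; only partitions leaving both
#' children at least `minsize` observations (and a non-constant
#' regressor) are admissible.
#'
#' @param y,x Node response and regressor.
#' @param z Splitting variable (factor, ordered or numeric).
#' @param minsize Minimum child size.
#' @return List with `left_levels` (categorical) or `cutpoint` (numeric),
#'   and `objective`; or `NULL` when no admissible partition exists.
#' @export
search_split <- function(y, x, z, minsize = 20L) {
  child_rss <- function(idx) {
    if (sum(idx) < minsize || sum(!idx) < minsize) return(NA_real_)
    if (stats::sd(x[idx]) == 0 || stats::sd(x[!idx]) == 0) return(NA_real_)
    sum(stats::.lm.fit(cbind(1, x[idx]), y[idx])$residuals^2) +
      sum(stats::.lm.fit(cbind(1, x[!idx]), y[!idx])$residuals^2)
  }
  if (is.factor(z) && !is.ordered(z)) {
    lev <- levels(droplevels(z))
    C <- length(lev)
    if (C < 2) return(NULL)
    zc <- as.character(z)
    # canonical enumeration: subsets of lev[-1] joined with lev[1] absent/...
    subsets <- unlist(lapply(seq_len(C - 1), function(sz)
      utils::combn(lev[-1], sz, simplify = FALSE)), recursive = FALSE)
    best <- NULL
    for (s in subsets) {
      left <- setdiff(lev, s)  # left set always contains the first level
      obj <- child_rss(zc %in% left)
      if (!is.na(obj) && (is.null(best) || obj < best$objective)) {
        best <- list(left_levels = left, objective = obj)
      }
    }
    best
  } else {
    zn <- as.numeric(z)
    vals <- sort(unique(zn))
    if (length(vals) < 2) return(NULL)
    cuts <- (vals[-1] + vals[-length(vals)]) / 2
    best <- NULL
    for (cp in cuts) {
      obj <- child_rss(zn <= cp)
      if (!is.na(obj) && (is.null(best) || obj < best$objective)) {
        best <- list(cutpoint = cp, objective = obj)
      }
    }
    best
  }
}

#' Grow a model-based recursive partitioning tree
#'
#' The node cycle fits the linear model, tests every candidate modifier
#' for parameter instability, selects the most unstable variable under
#' the Bonferroni-adjusted level, finds the RSS-optimal admissible binary
#' split, and recurses until the depth cap, minimum node size, or a
#' non-significant instability test stops it.
#'
#' @param y Numeric response (typically a z-standardized distress score).
#' @param x Numeric regressor (typically the negated centered SSQN score,
#'   so positive slopes mean more distress per unit decrease in support).
#' @param Z Data frame of candidate effect modifiers (factors or
#'   ordered/numeric); no missing values.
#' @param control A [mob_control()].
#' @return An object of class `"mob_tree"`.
#' @export
#' @examples
#' set.seed(1)
#' n <- 300
#' g <- factor(sample(c("a", "b"), n, TRUE))
#' x <- rnorm(n)
#' y <- ifelse(g == "a", 1 + x, 1 - x) + rnorm(n, sd = 0.3)
#' tree <- mob_grow(y, x, data.frame(g = g), mob_control(alpha = 0.05))
#' tree_leaves(tree)
mob_grow <- function(y, x, Z, control = mob_control()) {
  Z <- as.data.frame(Z)
  if (anyNA(Z) || anyNA(y) || anyNA(x)) {
    stop("mob_grow requires complete data; impute upstream", call. = FALSE)
  }
  stopifnot(nrow(Z) == length(y), length(x) == length(y))
  counter <- new.env()
  counter$id <- 0L
  root <- grow_node(y, x, Z, control, depth = 1L, counter = counter)
  structure(list(root = root, control = control, n = length(y),
                 variables = names(Z)),
            class = "mob_tree")
}

grow_node <- function(y, x, Z, control, depth, counter) {
  counter$id <- counter$id + 1L
  node <- list(id = counter$id, depth = depth, n = length(y))
  model <- fit_node_model(y, x)
  node$coef <- model$theta
  node$rss <- model$rss

  make_leaf <- function(node, why) {
    node$split <- NULL
    node$kids <- NULL
    node$stop_reason <- why
    node
  }
  if (depth >= control$maxdepth) return(make_leaf(node, "maxdepth"))
  if (length(y) < 2 * control$minsize) return(make_leaf(node, "minsize"))

  tests <- purrr::map_dfr(names(Z), function(v) {
    z <- Z[[v]]
    res <- tryCatch({
      if (is.factor(z) && !is.ordered(z)) {
        if (nlevels(droplevels(z)) < 2) return(NULL)
        instability_test_categorical(model, z)
      } else {
        instability_test_ordered(model, z, trim = control$trim,
                                 n_mc = control$n_mc,
                                 seed = control$seed + node$id)
      }
    }, error = function(e) NULL)
    if (is.null(res)) return(NULL)
    dplyr::mutate(res, variable = v, .before = 1)
  })
  if (nrow(tests) == 0) return(make_leaf(node, "no testable modifier"))
  m <- nrow(tests)
  tests$p_adj <- if (control$bonferroni) pmin(1, m * tests$p_raw) else tests$p_raw
  node$tests <- tests

  sel <- select_variable(tests[c("variable", "statistic", "p_raw")], control)
  if (is.null(sel)) return(make_leaf(node, "no significant instability"))
  spl <- search_split(y, x, Z[[sel$variable]], minsize = control$minsize)
  if (is.null(spl)) return(make_leaf(node, "no admissible split"))

  if (!is.null(spl$left_levels)) {
    spl$right_levels <- setdiff(levels(droplevels(Z[[sel$variable]])),
                                spl$left_levels)
  }
  node$split <- c(list(variable = sel$variable, p_raw = sel$p_raw,
                       p_adj = sel$p_adj, statistic = sel$statistic), spl)
  idx <- split_index(Z[[sel$variable]], node$split)
  node$kids <- list(
    grow_node(y[idx], x[idx], Z[idx, , drop = FALSE], control, depth + 1L, counter),
    grow_node(y[!idx], x[!idx], Z[!idx, , drop = FALSE], control, depth + 1L, counter)
  )
  node
}

split_index <- function(z, split) {
  if (!is.null(split$left_levels)) {
    as.character(z) %in% split$left_levels
  } else {
    as.numeric(z) <= split$cutpoint
  }
}

#' Leaves of a fitted tree
#'
#' @param tree A `"mob_tree"` (or the tree inside a `"palm_tree"`).
#' @return Tibble with `leaf_id`, `n`, `intercept`, `slope`, `rss` and a
#'   human-readable `path` of split conditions from the root.
#' @export
tree_leaves <- function(tree) {
  if (inherits(tree, "palm_tree")) tree <- tree$tree
  stopifnot(inherits(tree, "mob_tree"))
  walk <- function(node, path) {
    if (is.null(node$kids)) {
      return(tibble::tibble(
        leaf_id = node$id, n = node$n,
        intercept = unname(node$coef[1]), slope = unname(node$coef[2]),
        rss = node$rss,
        path = if (length(path)) paste(path, collapse = " & ") else "full sample"
      ))
    }
    sp <- node$split
    lp <- describe_condition(sp, TRUE)
    rp <- describe_condition(sp, FALSE)
    dplyr::bind_rows(walk(node$kids[[1]], c(path, lp)),
                     walk(node$kids[[2]], c(path, rp)))
  }
  walk(tree$root, character(0))
}

describe_condition <- function(split, left) {
  if (!is.null(split$left_levels)) {
    lev <- if (left) split$left_levels else
      split$right_levels %||% paste0("not ", split$left_levels)
    paste0(split$variable, " in {", paste(lev, collapse = ", "), "}")
  } else {
    paste0(split$variable, if (left) " <= " else " > ", signif(split$cutpoint, 4))
  }
}

#' Leaf membership of new observations
#'
#' @param tree A `"mob_tree"`.
#' @param Z Data frame of modifier values.
#' @return Integer vector of leaf ids.
#' @export
predict_leaf <- function(tree, Z) {
  if (inherits(tree, "palm_tree")) tree <- tree$tree
  stopifnot(inherits(tree, "mob_tree"))
  Z <- as.data.frame(Z)
  out <- integer(nrow(Z))
  walk <- function(node, idx) {
    if (is.null(node$kids)) {
      out[idx] <<- node$id
      return(invisible())
    }
    take <- split_index(Z[[node$split$variable]][idx], node$split)
    walk(node$kids[[1]], idx[take])
    walk(node$kids[[2]], idx[!take])
  }
  walk(tree$root, seq_len(nrow(Z)))
  out
}

#' @export
print.mob_tree <- function(x, ...) {
  cat("Model-based recursive partitioning tree (n =", x$n, ")\n")
  walk <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (is.null(node$kids)) {
      cat(sprintf("%s[%d] leaf: n=%d, intercept=%.3f, slope=%.3f\n",
                  pad, node$id, node$n, node$coef[1], node$coef[2]))
    } else {
      cat(sprintf("%s[%d] split on %s (p_adj=%.4g), n=%d\n",
                  pad, node$id, node$split$variable, node$split$p_adj, node$n))
      walk(node$kids[[1]], indent + 1)
      walk(node$kids[[2]], indent + 1)
    }
  }
  walk(x$root, 0)
  invisible(x)
}

# depth-first list of all nodes (internal)
tree_nodes <- function(tree) {
  out <- list()
  walk <- function(node) {
    out[[length(out) + 1]] <<- node
    if (!is.null(node$kids)) {
      walk(node$kids[[1]]); walk(node$kids[[2]])
    }
  }
  walk(tree$root)
  out
}
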