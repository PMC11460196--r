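# Shared fixtures and independent oracles for the test suite.

small_config <- function(n = 400, seed = 1L, ...) {
  cfg <- scale_scenario(scenario_config(seed = seed, ...), n)
  cfg
}

# independent OLS oracle: explicit normal equations
ols_oracle <- function(y, x) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# brute-force evaluation of the categorical fluctuation statistic,
# written directly from the formula with explicit loops
brute_instability_cat <- function(y, x, z) {
  co <- ols_oracle(y, x)
  r <- y - co[1] - co[2] * x
  psi <- cbind(r, r * x)
  n <- length(y)
  V <- matrix(0, 2, 2)
  for (i in seq_len(n)) V <- V + psi[i, ] %*% t(psi[i, ])
  V <- V / n
  Vi <- solve(V)
  stat <- 0
  for (lev in unique(as.character(z))) {
    idx <- which(as.character(z) == lev)
    S <- colSums(psi[idx, , drop = FALSE])
    stat <- stat + drop(t(S) %*% Vi %*% S) / length(idx)
  }
  stat
}

# brute-force split search: refit both children for every candidate
brute_split_cat <- function(y, x, z, minsize) {
  lev <- levels(droplevels(factor(z)))
  best <- NULL
  subsets <- unlist(lapply(seq_len(length(lev) - 1), function(sz)
    utils::combn(lev[-1], sz, simplify = FALSE)), recursive = FALSE)
  for (s in subsets) {
    left <- setdiff(lev, s)
    idx <- as.character(z) %in% left
    if (sum(idx) < minsize || sum(!idx) < minsize) next
    if (sd(x[idx]) == 0 || sd(x[!idx]) == 0) next
    rss <- function(sel) {
      co <- ols_oracle(y[sel], x[sel])
      sum((y[sel] - co[1] - co[2] * x[sel])^2)
    }
    obj <- rss(idx) + rss(!idx)
    if (is.null(best) || obj < best$objective) {
      best <- list(left_levels = left, objective = obj)
    }
  }
  best
}

# tree signature for bit-identity comparisons
tree_signature <- function(tree) {
  if (inherits(tree, "palm_tree")) tree <- tree$tree
  walk <- function(node) {
    if (is.null(node$kids)) {
      return(sprintf("leaf(n=%d,a=%.12f,b=%.12f)", node$n,
                     node$coef[1], node$coef[2]))
    }
    sp <- node$split
    lab <- if (!is.null(sp$left_levels)) {
      paste(sp$left_levels, collapse = ",")
    } else sprintf("%.12f", sp$cutpoint)
    sprintf("split(%s:%s)[%s|%s]", sp$variable, lab,
            walk(node$kids[[1]]), walk(node$kids[[2]]))
  }
  walk(tree$root)
}

ssq_col_names <- function() {
  as.vector(sapply(1:5, function(p) paste0("ssq_p", p, "_i", 1:4)))
}

dass_col_names <- function() sprintf("dass_%02d", 1:21)
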