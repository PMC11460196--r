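test_that("the node model reproduces exact and degenerate fits", {
  x <- c(1, 2, 3, 4, 5)
  m <- fit_node_model(2 + 3 * x, x)
  expect_equal(unname(m$theta), c(2, 3), tolerance = 1e-12)
  expect_lt(m$rss, 1e-20)
  # symmetric x, constant y: slope exactly zero
  x2 <- c(-2, -1, 0, 1, 2)
  m2 <- fit_node_model(rep(1, 5), x2)
  expect_equal(unname(m2$theta[2]), 0, tolerance = 1e-14)
  expect_error(fit_node_model(rnorm(5), rep(1, 5)), "constant")
  # first-order conditions: score columns sum to zero
  set.seed(1)
  m3 <- fit_node_model(rnorm(100), rnorm(100))
  expect_lt(max(abs(colSums(m3$score_rows))), 1e-8)
})

test_that("OLS matches the normal-equations oracle to 1e-10", {
  set.seed(11)
  for (rep in 1:10) {
    x <- rnorm(50)
    y <- 0.5 - 1.2 * x + rnorm(50)
    m <- fit_node_model(y, x)
    expect_lt(max(abs(m$theta - ols_oracle(y, x))), 1e-10)
  }
})

test_that("categorical instability statistic matches a brute-force oracle", {
  # fixed 8-observation worked instance
  y <- c(1.2, 0.4, -0.3, 2.2, 0.9, -1.1, 0.05, 1.6)
  x <- c(0.5, -1.0, 0.2, 1.4, -0.7, 0.3, -0.2, 0.9)
  z <- factor(c("a", "a", "b", "b", "a", "b", "b", "a"))
  m <- fit_node_model(y, x)
  res <- instability_test_categorical(m, z)
  expect_lt(abs(res$statistic - brute_instability_cat(y, x, z)), 1e-10)
  expect_identical(res$df, 2)
  # random instances, 2- and 3-level modifiers
  set.seed(13)
  for (C in 2:3) {
    for (rep in 1:8) {
      x <- rnorm(40); y <- 1 + x + rnorm(40)
      z <- factor(sample(letters[1:C], 40, replace = TRUE))
      m <- fit_node_model(y, x)
      res <- instability_test_categorical(m, z)
      expect_lt(abs(res$statistic - brute_instability_cat(y, x, z)), 1e-10)
      expect_identical(res$df, 2 * (C - 1))
    }
  }
})

test_that("zero fluctuation gives statistic 0 and p-value 1", {
  # duplicating each observation into both groups makes the level sums
  # equal to half the total score, which is exactly zero
  set.seed(14)
  x0 <- rnorm(20); y0 <- 0.3 + 0.8 * x0 + rnorm(20)
  y <- c(y0, y0); x <- c(x0, x0)
  z <- factor(rep(c("a", "b"), each = 20))
  m <- fit_node_model(y, x)
  res <- instability_test_categorical(m, z)
  expect_lt(res$statistic, 1e-16)
  expect_equal(res$p_raw, 1)
})

test_that("categorical test holds its nominal size", {
  set.seed(101)
  reps <- 2000
  n <- 500
  rej <- logical(reps)
  for (b in seq_len(reps)) {
    x <- rnorm(n)
    y <- 0.2 + 0.5 * x + rnorm(n)
    z <- factor(sample(c("a", "b"), n, replace = TRUE))
    res <- instability_test_categorical(fit_node_model(y, x), z)
    rej[b] <- res$p_raw <= 0.05
  }
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.065)
})

test_that("ordered instability statistic matches a cumulative-sum oracle", {
  set.seed(15)
  n <- 60
  x <- rnorm(n); y <- 1 + 0.5 * x + rnorm(n)
  z <- sample(seq_len(10), n, replace = TRUE)
  m <- fit_node_model(y, x)
  res <- instability_test_ordered(m, z, trim = 0.1, n_mc = 200, seed = 2)
  # oracle: decorrelated cumulative sums evaluated by direct loops
  psi <- m$score_rows
  V <- crossprod(psi) / n
  ev <- eigen(V, symmetric = TRUE)
  Vih <- ev$vectors %*% diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
  ordix <- order(z)
  zs <- z[ordix]
  W <- psi[ordix, ] %*% Vih
  stat_oracle <- -Inf
  for (i in seq_len(n - 1)) {
    if (zs[i] == zs[i + 1]) next
    t_i <- i / n
    if (t_i < 0.1 || t_i > 0.9) next
    S <- colSums(W[seq_len(i), , drop = FALSE]) / sqrt(n)
    stat_oracle <- max(stat_oracle, sum(S^2) / (t_i * (1 - t_i)))
  }
  expect_lt(abs(res$statistic - stat_oracle), 1e-10)
})

test_that("an exact fit yields a degenerate ordered test", {
  x <- 1:30
  res <- instability_test_ordered(fit_node_model(2 + 0.1 * x, x),
                                  z = rep(1:10, 3), n_mc = 100)
  expect_identical(res$statistic, 0)
  expect_identical(res$p_raw, 1)
})

test_that("ordered test size is near nominal under the null", {
  set.seed(77)
  reps <- 600
  n <- 250
  rej <- logical(reps)
  for (b in seq_len(reps)) {
    x <- rnorm(n)
    y <- 0.1 + 0.3 * x + rnorm(n)
    z <- sample(seq_len(20), n, replace = TRUE)
    res <- instability_test_ordered(fit_node_model(y, x), z,
                                    n_mc = 600, seed = b)
    rej[b] <- res$p_raw <= 0.05
  }
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.07)
})

test_that("variable selection applies Bonferroni and the stated tie-breaks", {
  res <- tibble::tibble(variable = c("v1", "v2", "v3"),
                        statistic = c(10, 3, 1),
                        p_raw = c(0.001, 0.2, 0.9))
  sel <- select_variable(res, mob_control(alpha = 0.05))
  expect_identical(sel$variable, "v1")
  expect_equal(sel$p_adj, 0.003)
  # all null at alpha 0.05: nothing selected
  res2 <- dplyr::mutate(res, p_raw = 0.5)
  expect_null(select_variable(res2, mob_control(alpha = 0.05)))
  # exploratory alpha = 1: the largest statistic wins the tie
  sel3 <- select_variable(res2, mob_control(alpha = 1))
  expect_identical(sel3$variable, "v1")
})

test_that("split search equals exhaustive enumeration", {
  set.seed(16)
  # binary modifier: the single possible partition
  z <- factor(sample(c("p", "q"), 60, replace = TRUE))
  x <- rnorm(60); y <- rnorm(60)
  sp <- search_split(y, x, z, minsize = 10)
  expect_setequal(sp$left_levels, "p")
  # 3-level modifier against the brute-force oracle
  for (rep in 1:10) {
    z3 <- factor(sample(c("a", "b", "c"), 60, replace = TRUE))
    y3 <- rnorm(60) + (z3 == "a")
    sp3 <- search_split(y3, x, z3, minsize = 5)
    or3 <- brute_split_cat(y3, x, z3, minsize = 5)
    expect_setequal(sp3$left_levels, or3$left_levels)
    expect_equal(sp3$objective, or3$objective, tolerance = 1e-12)
  }
})

test_that("split search recovers a planted level grouping", {
  set.seed(17)
  n <- 300
  z <- factor(sample(c("A", "B", "C"), n, replace = TRUE))
  x <- rnorm(n)
  y <- ifelse(z == "A", 1 + x, 1 - x) + rnorm(n, sd = 0.05)
  sp <- search_split(y, x, z, minsize = 20)
  expect_setequal(sp$left_levels, "A")
})

test_that("numeric split search scans midpoints between distinct values", {
  set.seed(18)
  n <- 200
  z <- sample(1:6, n, replace = TRUE)
  x <- rnorm(n)
  y <- ifelse(z <= 3, x, -x) + rnorm(n, sd = 0.1)
  sp <- search_split(y, x, z, minsize = 20)
  expect_equal(sp$cutpoint, 3.5)
})

test_that("grown trees respect the depth cap and conserve observations", {
  set.seed(19)
  n <- 600L
  Z <- data.frame(g = factor(sample(c("m", "f"), n, TRUE)),
                  e = factor(sample(c("lo", "mid", "hi"), n, TRUE)))
  x <- rnorm(n)
  y <- ifelse(Z$g == "m", 0.5 + 0.8 * x, -0.5 - 0.2 * x) + rnorm(n)
  tree <- mob_grow(y, x, Z, mob_control(alpha = 1, maxdepth = 3))
  lv <- tree_leaves(tree)
  expect_lte(nrow(lv), 4)
  expect_identical(sum(lv$n), n)
  # maxdepth = 1 forces a single leaf
  tree1 <- mob_grow(y, x, Z, mob_control(maxdepth = 1))
  expect_identical(nrow(tree_leaves(tree1)), 1L)
  expect_identical(tree_leaves(tree1)$path, "full sample")
  # missing modifiers are rejected
  Zna <- Z; Zna$g[1] <- NA
  expect_error(mob_grow(y, x, Zna, mob_control()), "complete")
})

test_that("total leaf RSS never increases along refinements", {
  set.seed(20)
  n <- 500
  Z <- data.frame(a = factor(sample(c("x", "y"), n, TRUE)),
                  b = factor(sample(c("u", "v", "w"), n, TRUE)))
  x <- rnorm(n)
  y <- 0.3 * x + rnorm(n) + 0.4 * (Z$a == "x") * x
  tree <- mob_grow(y, x, Z, mob_control(alpha = 1, maxdepth = 3))
  check <- function(node) {
    if (is.null(node$kids)) return(invisible())
    kid_rss <- node$kids[[1]]$rss + node$kids[[2]]$rss
    expect_lte(kid_rss, node$rss + 1e-8)
    check(node$kids[[1]]); check(node$kids[[2]])
  }
  check(tree$root)
})

test_that("grow agrees with exhaustive search on all tiny binary instances", {
  set.seed(21)
  for (n in c(8, 10, 12)) {
    for (rep in 1:12) {
      x <- rnorm(n)
      y <- rnorm(n)
      z <- factor(sample(c("a", "b"), n, replace = TRUE))
      if (min(table(z)) < 3) next
      minsize <- 3L
      sp <- search_split(y, x, z, minsize = minsize)
      or <- brute_split_cat(y, x, z, minsize = minsize)
      if (is.null(or)) {
        expect_null(sp)
      } else {
        expect_setequal(sp$left_levels, or$left_levels)
        expect_equal(sp$objective, or$objective, tolerance = 1e-12)
      }
    }
  }
})

test_that("homogeneous data rarely split at alpha 0.05", {
  set.seed(22)
  n_seeds <- 40
  splits <- vapply(seq_len(n_seeds), function(s) {
    set.seed(1000 + s)
    n <- 300
    Z <- data.frame(a = factor(sample(c("x", "y"), n, TRUE)),
                    b = factor(sample(c("u", "v", "w"), n, TRUE)))
    x <- rnorm(n)
    y <- 0.5 + 0.4 * x + rnorm(n)
    tree <- mob_grow(y, x, Z, mob_control(alpha = 0.05))
    nrow(tree_leaves(tree)) > 1
  }, logical(1))
  expect_gte(mean(!splits), 0.9)
})

test_that("the full procedure controls the family-wise false-split rate", {
  set.seed(23)
  reps <- 2000
  n <- 300
  any_split <- logical(reps)
  for (b in seq_len(reps)) {
    Z <- data.frame(v1 = factor(sample(c("a", "b"), n, TRUE)),
                    v2 = factor(sample(c("a", "b", "c"), n, TRUE)),
                    v3 = factor(sample(c("a", "b"), n, TRUE)),
                    v4 = factor(sample(c("a", "b", "c"), n, TRUE)))
    x <- rnorm(n)
    y <- 0.2 * x + rnorm(n)
    tree <- mob_grow(y, x, Z, mob_control(alpha = 0.05, maxdepth = 2))
    any_split[b] <- nrow(tree_leaves(tree)) > 1
  }
  expect_lte(mean(any_split), 0.07)
})

test_that("a planted slope difference is reliably detected at cohort scale", {
  hits <- vapply(1:10, function(s) {
    set.seed(3000 + s)
    n <- 4466
    Z <- data.frame(g = factor(sample(c("w", "m"), n, TRUE)),
                    e = factor(sample(c("lo", "mid", "hi"), n, TRUE)))
    x <- rnorm(n)
    slope <- ifelse(Z$g == "w", 0.20, 0.08)   # 0.12 z-unit contrast
    y <- slope * x + rnorm(n)
    tree <- mob_grow(y, x, Z, mob_control(alpha = 1, maxdepth = 2))
    !is.null(tree$root$split) && tree$root$split$variable == "g"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
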