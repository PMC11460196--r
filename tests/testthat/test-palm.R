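test_that("PALM without globals reduces to plain MOB bit-identically", {
  set.seed(40)
  n <- 500
  Z <- data.frame(g = factor(sample(c("w", "m"), n, TRUE)),
                  e = factor(sample(c("lo", "mid", "hi"), n, TRUE)))
  x <- rnorm(n)
  y <- ifelse(Z$g == "w", 0.5 + 0.6 * x, -0.5 - 0.3 * x) + rnorm(n)
  ctrl <- palm_control(alpha = 1, maxdepth = 3, seed = 11)
  fit <- fit_palm(y, x, G = NULL, Z = Z, control = ctrl)
  tree <- mob_grow(y, x, Z, ctrl)
  expect_identical(tree_signature(fit), tree_signature(tree))
  expect_identical(fit$n_iter, 2L)   # second pass only confirms the fixed point
  # leaf estimates equal per-leaf OLS
  leaf <- predict_leaf(tree, Z)
  for (i in seq_len(nrow(fit$leaf_estimates))) {
    le <- fit$leaf_estimates[i, ]
    idx <- leaf == le$leaf_id
    co <- ols_oracle(y[idx], x[idx])
    expect_lt(abs(le$slope - co[2]), 1e-10)
    expect_lt(abs(le$intercept - co[1]), 1e-10)
  }
})

test_that("a pure global signal is fully captured by gamma", {
  set.seed(41)
  n <- 400
  G <- data.frame(u = factor(sample(c("p", "q"), n, TRUE)),
                  v = factor(sample(c("r", "s", "t"), n, TRUE)))
  Z <- data.frame(g = factor(sample(c("a", "b"), n, TRUE)))
  x <- rnorm(n)
  cvec <- c(uq = 0.7, vs = -0.4, vt = 0.9)
  y <- 0.7 * (G$u == "q") - 0.4 * (G$v == "s") + 0.9 * (G$v == "t")
  fit <- suppressWarnings(
    fit_palm(y, x, G, Z, palm_control(alpha = 0.05, n_mc = 300)))
  expect_identical(nrow(fit$leaf_estimates), 1L)
  expect_lt(abs(fit$gamma[["uq"]] - 0.7), 1e-6)
  expect_lt(abs(fit$gamma[["vs"]] + 0.4), 1e-6)
  expect_lt(abs(fit$gamma[["vt"]] - 0.9), 1e-6)
  expect_lt(abs(fit$leaf_estimates$slope), 1e-6)
})

test_that("the joint objective is monotone over outer iterations", {
  set.seed(42)
  n <- 800
  G <- data.frame(u = factor(sample(c("p", "q"), n, TRUE)))
  Z <- data.frame(g = factor(sample(c("a", "b"), n, TRUE)),
                  h = factor(sample(c("c", "d", "e"), n, TRUE)))
  x <- rnorm(n)
  y <- ifelse(Z$g == "a", 0.3 + 0.5 * x, -0.3 - 0.5 * x) +
    0.4 * (G$u == "q") + rnorm(n)
  fit <- fit_palm(y, x, G, Z, palm_control(alpha = 1, maxdepth = 2))
  tr <- fit$objective_trace
  expect_true(all(diff(tr) <= 1e-10 * tr[1]))
  expect_true(fit$converged)
})

test_that("confidence intervals follow the normal-quantile arithmetic", {
  # forced arithmetic: 0.16 +/- 1.959964 * 0.0204 -> (0.12, 0.20) at 2 dp
  q <- qnorm(0.975)
  lo <- 0.16 - q * 0.0204
  hi <- 0.16 + q * 0.0204
  expect_identical(sprintf("%.2f", lo), "0.12")
  expect_identical(sprintf("%.2f", hi), "0.20")
  # an exact fit collapses the interval onto the estimate
  set.seed(43)
  n <- 120
  Z <- data.frame(g = factor(sample(c("a", "b"), n, TRUE)))
  x <- rnorm(n)
  y <- 1 + 2 * x
  fit <- suppressWarnings(
    fit_palm(y, x, NULL, Z, palm_control(alpha = 0.05, n_mc = 200)))
  ci <- leaf_confidence_intervals(fit)
  expect_equal(ci$conf.low, ci$conf.high, tolerance = 1e-6)
  expect_equal(ci$slope, 2, tolerance = 1e-8)
})

test_that("tidy, glance and the report table expose the fit coherently", {
  set.seed(44)
  n <- 300L
  Z <- data.frame(g = factor(sample(c("a", "b"), n, TRUE)))
  x <- rnorm(n)
  y <- 0.2 * x + rnorm(n)
  fit <- suppressWarnings(
    fit_palm(y, x, NULL, Z, palm_control(alpha = 0.05, n_mc = 300)))
  td <- tidy(fit)
  expect_identical(td$subgroup, "full sample")
  gl <- glance(fit)
  expect_identical(gl$nobs, n)
  expect_identical(gl$n.leaves, 1L)
  rt <- report_table(fit)
  expect_match(rt$ci, "^\\(-?\\d+\\.\\d{2}, -?\\d+\\.\\d{2}\\)$")
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("the reported slope is positive per unit decrease in support", {
  set.seed(45)
  n <- 400
  ssqn <- runif(n, 0, 4)
  z_out <- 1.0 - 0.16 * ssqn + rnorm(n, sd = 0.1)  # distress falls with support
  x <- -(ssqn - mean(ssqn))
  Z <- data.frame(g = factor(sample(c("a", "b"), n, TRUE)))
  fit <- suppressWarnings(
    fit_palm(z_out, x, NULL, Z, palm_control(alpha = 0.05, n_mc = 200)))
  expect_gt(fit$leaf_estimates$slope, 0.1)
  expect_lt(abs(fit$leaf_estimates$slope - 0.16), 0.03)
})

test_that("global coefficients are recovered within 2 SE at scale", {
  # marital carries a planted +0.1 z shift per non-married level and is
  # never split on, so its global coefficients are identified; continuous
  # (unrounded) scores keep the planted shifts exact. Coverage of the
  # 2 SE band is a rate over seeds: nominal ~95%, asserted >= 90% over
  # 20 seeds x 2 coefficients to allow binomial noise.
  inside <- unlist(lapply(1:20, function(s) {
    cfg <- small_config(1500, seed = 1000 + s)
    demo <- generate_ssq(cfg, generate_demographics(cfg))
    coh <- generate_dass(cfg, demo, round_items = FALSE)
    tr <- cohort_truth(coh)
    inc <- !tr$empty_dass
    raw <- coh$raw_stress[inc]
    y <- (raw - mean(raw)) / sd(raw)
    ssqn <- tr$true_ssqn[inc]
    x <- -(ssqn - mean(ssqn))
    covars <- as.data.frame(coh[inc, c("gender", "age_group", "education",
                                       "marital")])
    fit <- suppressWarnings(fit_palm(y, x, G = covars, Z = covars,
                                     control = palm_control()))
    planted <- 0.1 * cfg$dass_norms$sd[3] / sd(raw)
    vapply(c("maritaldivorced", "maritalunmarried"), function(nm)
      abs(fit$gamma[[nm]] - planted) < 2 * fit$gamma_se[[nm]], logical(1))
  }))
  expect_gte(mean(inside), 0.90)
})

test_that("confidence intervals cover planted slopes at the expected rate", {
  # reduced-scale coverage study (40 seeds): binomial 95% band around the
  # nominal 90-97% post-selection coverage range
  covered <- vapply(1:40, function(s) {
    set.seed(500 + s)
    n <- 1200
    Z <- data.frame(g = factor(sample(c("w", "m"), n, TRUE, prob = c(.8, .2))),
                    e = factor(sample(c("lo", "hi"), n, TRUE)))
    x <- rnorm(n, sd = 0.65)
    slope <- ifelse(Z$g == "w", 0.20, 0.08) + 0.3 * (Z$g == "w")
    y <- 0.4 * (Z$g == "w") + slope * x + rnorm(n)
    fit <- fit_palm(y, x, NULL, Z, palm_control(alpha = 1, maxdepth = 2))
    td <- tidy(fit)
    row <- td[grepl("g in \\{w\\}", td$subgroup), ]
    if (nrow(row) != 1) return(NA)
    row$conf.low <= 0.50 && 0.50 <= row$conf.high
  }, logical(1))
  covered <- covered[!is.na(covered)]
  expect_gte(mean(covered), 0.80)
  expect_gte(length(covered), 30)
})

test_that("degenerate joint designs raise errors", {
  set.seed(46)
  n <- 50
  Z <- data.frame(g = factor(sample(c("a", "b"), n, TRUE)))
  x <- rnorm(n)
  y <- rnorm(n)
  G <- data.frame(u = factor(rep("p", n)))   # constant factor
  expect_error(
    suppressWarnings(fit_palm(y, x, G, Z, palm_control(alpha = 0.05,
                                                       n_mc = 100))))
})
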