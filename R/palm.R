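#' Control parameters for PALM trees
#'
#' Extends [mob_control()] with the outer-loop convergence settings of
#' the alternating tree / joint-regression algorithm.
#'
#' @inheritParams mob_control
#' @param max_outer_iter Maximum alternations between tree growing and
#'   the joint fit.
#' @param tol Relative change in the joint residual sum of squares below
#'   which the alternation stops.
#' @param coef_tol Maximum absolute coefficient change below which the
#'   alternation stops.
#' @return A list of class `c("palm_control", "mob_control")`.
#' @export
palm_control <- function(alpha = 1, maxdepth = 3L, minsize = 20L,
                         bonferroni = TRUE, trim = 0.1, n_mc = 10000L,
                         seed = 1L, max_outer_iter = 100L, tol = 1e-8,
                         coef_tol = 1e-6) {
  ctrl <- mob_control(alpha = alpha, maxdepth = maxdepth, minsize = minsize,
                      bonferroni = bonferroni, trim = trim, n_mc = n_mc,
                      seed = seed)
  stopifnot(tol > 0, coef_tol > 0, max_outer_iter >= 1)
  ctrl$max_outer_iter <- as.integer(max_outer_iter)
  ctrl$tol <- tol
  ctrl$coef_tol <- coef_tol
  class(ctrl) <- c("palm_control", "mob_control")
  ctrl
}

#' Fit a partially additive linear model tree
#'
#' MOB with global additive covariate effects held constant across
#' subgroups. The algorithm alternates (i) adjusting the response for the
#' current global effects, (ii) growing a MOB tree on the adjusted
#' response, and (iii) a joint OLS of the raw response on leaf-wise
#' intercepts and slopes plus the dummy-coded global covariates, until
#' the joint residual sum of squares stabilizes. Global covariates that
#' are collinear with the leaf structure (e.g. a dummy fully explained by
#' the splits) are dropped from the global part with a warning and
#' absorbed by the leaf coefficients.
#'
#' @param y Numeric response (z-standardized distress score).
#' @param x Numeric regressor (negated centered SSQN: positive slopes
#'   mean more distress per unit decrease in support).
#' @param G Data frame of global adjustment covariates (factors), or
#'   `NULL`/zero-column for a plain MOB fit.
#' @param Z Data frame of candidate effect modifiers.
#' @param control A [palm_control()].
#' @return Object of class `"palm_tree"`: the final tree, global
#'   coefficients `gamma`, per-leaf estimates with standard errors, the
#'   RSS trace, and convergence information.
#' @export
#' @examples
#' set.seed(2)
#' n <- 400
#' g <- factor(sample(c("a", "b"), n, TRUE))
#' u <- factor(sample(c("p", "q"), n, TRUE))
#' x <- rnorm(n)
#' y <- ifelse(g == "a", 0.5 + x, -0.5 - x) + 0.3 * (u == "q") + rnorm(n)
#' fit <- fit_palm(y, x, data.frame(u = u), data.frame(g = g),
#'                 palm_control(alpha = 0.05, n_mc = 500))
#' tidy(fit)
fit_palm <- function(y, x, G, Z, control = palm_control()) {
  Z <- as.data.frame(Z)
  n <- length(y)
  has_G <- !is.null(G) && NCOL(G) > 0
  if (has_G) {
    G <- as.data.frame(G)
    if (anyNA(G)) stop("global covariates must be complete", call. = FALSE)
    Gmat <- stats::model.matrix(~ ., data = G)[, -1, drop = FALSE]
    if (qr(Gmat)$rank < ncol(Gmat)) {
      stop("global design is rank deficient after dummy coding", call. = FALSE)
    }
  } else {
    Gmat <- matrix(numeric(0), n, 0)
  }
  gamma <- rep(0, ncol(Gmat))
  names(gamma) <- colnames(Gmat)

  trace <- numeric(0)
  converged <- FALSE
  dropped <- character(0)
  tree <- NULL
  joint <- NULL
  prev_coefs <- NULL
  for (iter in seq_len(control$max_outer_iter)) {
    y_adj <- y - as.vector(Gmat %*% gamma)
    tree <- mob_grow(y_adj, x, Z, control)
    leaf <- factor(predict_leaf(tree, Z))
    X <- leaf_design(leaf, x)
    fit <- stats::lm.fit(cbind(X, Gmat), y)
    coefs <- fit$coefficients
    g_new <- coefs[seq_len(ncol(Gmat)) + ncol(X)]
    if (anyNA(coefs[seq_len(ncol(X))])) {
      stop("joint design rank deficient in the leaf block (empty leaf?)",
           call. = FALSE)
    }
    na_g <- is.na(g_new)
    if (any(na_g)) {
      new_drop <- setdiff(names(gamma)[na_g], dropped)
      if (length(new_drop)) {
        warning("global column(s) collinear with the leaf structure, ",
                "absorbed by leaf coefficients: ",
                paste(new_drop, collapse = ", "), call. = FALSE)
        dropped <- union(dropped, new_drop)
      }
      g_new[na_g] <- 0
    }
    rss <- sum(fit$residuals^2)
    trace <- c(trace, rss)
    all_coefs <- c(coefs[seq_len(ncol(X))], g_new)
    delta_ok <- !is.null(prev_coefs) &&
      length(prev_coefs) == length(all_coefs) &&
      max(abs(prev_coefs - all_coefs)) < control$coef_tol
    rss_ok <- iter > 1 &&
      abs(trace[iter - 1] - rss) <= control$tol * max(trace[iter - 1], 1e-300)
    gamma <- g_new
    prev_coefs <- all_coefs
    joint <- fit
    if (rss_ok || delta_ok) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("PALM alternation did not converge in ", control$max_outer_iter,
            " iterations; returning last iterate", call. = FALSE)
  }

  # final joint fit without the absorbed global columns: full-rank design
  leaf <- factor(predict_leaf(tree, Z))
  X <- leaf_design(leaf, x)
  Gkeep <- Gmat[, setdiff(colnames(Gmat), dropped), drop = FALSE]
  Xfull <- cbind(X, Gkeep)
  p <- ncol(Xfull)
  rdf <- n - p
  if (rdf < 1) stop("zero residual degrees of freedom in the joint fit",
                    call. = FALSE)
  fin <- stats::lm.fit(Xfull, y)
  if (anyNA(fin$coefficients)) {
    stop("final joint design is rank deficient", call. = FALSE)
  }
  sigma2 <- sum(fin$residuals^2) / rdf
  covm <- solve(crossprod(Xfull)) * sigma2
  se <- sqrt(diag(covm))
  gamma_out <- stats::setNames(rep(0, ncol(Gmat)), colnames(Gmat))
  gamma_out[colnames(Gkeep)] <- fin$coefficients[colnames(Gkeep)]
  gamma_se <- stats::setNames(rep(NA_real_, ncol(Gmat)), colnames(Gmat))
  gamma_se[colnames(Gkeep)] <- se[colnames(Gkeep)]

  leaves <- tree_leaves(tree)
  lv <- levels(leaf)
  single <- nlevels(leaf) == 1
  icpt_nm <- if (single) "(Intercept)" else paste0("leaf", lv, "_intercept")
  slope_nm <- if (single) "x" else paste0("leaf", lv, "_slope")
  est <- tibble::tibble(
    leaf_id = as.integer(lv),
    n = as.vector(table(leaf)),
    intercept = unname(fin$coefficients[icpt_nm]),
    slope = unname(fin$coefficients[slope_nm]),
    slope_se = unname(se[slope_nm]),
    path = leaves$path[match(as.integer(lv), leaves$leaf_id)]
  )
  structure(list(tree = tree, gamma = gamma_out, gamma_se = gamma_se,
                 dropped_globals = dropped,
                 leaf_estimates = est, objective_trace = trace,
                 n_iter = length(trace), converged = converged,
                 n = n, sigma2 = sigma2,
                 control = control),
            class = "palm_tree")
}

leaf_design <- function(leaf, x) {
  if (nlevels(leaf) == 1) {
    X <- cbind(1, x)
    colnames(X) <- c("(Intercept)", "x")
  } else {
    L <- stats::model.matrix(~ 0 + leaf)
    X <- cbind(L, L * x)
    colnames(X) <- c(paste0("leaf", levels(leaf), "_intercept"),
                     paste0("leaf", levels(leaf), "_slope"))
  }
  X
}

#' Wald confidence intervals for the leaf slopes
#'
#' Normal-quantile intervals `slope +/- q * SE` from the final joint
#' model.
#'
#' @param model A fitted [fit_palm()] object.
#' @param level Confidence level (default 0.95).
#' @return The leaf-estimate tibble with `conf.low`, `conf.high` added.
#' @export
leaf_confidence_intervals <- function(model, level = 0.95) {
  stopifnot(inherits(model, "palm_tree"), level > 0, level < 1)
  q <- stats::qnorm(1 - (1 - level) / 2)
  dplyr::mutate(model$leaf_estimates,
                conf.low = .data$slope - q * .data$slope_se,
                conf.high = .data$slope + q * .data$slope_se)
}

#' @export
print.palm_tree <- function(x, ...) {
  cat("Partially additive linear model tree\n")
  cat("  n =", x$n, ", leaves =", nrow(x$leaf_estimates),
      ", outer iterations =", x$n_iter,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  if (length(x$gamma)) {
    cat("  global coefficients:\n")
    g <- x$gamma
    for (nm in names(g)) cat(sprintf("    %s: %.4f%s\n", nm, g[nm],
      if (nm %in% x$dropped_globals) " [absorbed by leaves]" else ""))
  }
  print(x$tree)
  invisible(x)
}

#' Tidy a fitted PALM tree
#'
#' One row per leaf with the subgroup definition, the slope of the
#' distress z-score per unit decrease in the SSQN support score, its
#' standard error and Wald confidence interval.
#'
#' @param x A `"palm_tree"`.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A tibble with columns `leaf_id`, `subgroup`, `n`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @method tidy palm_tree
#' @export
tidy.palm_tree <- function(x, conf.level = 0.95, ...) {
  ci <- leaf_confidence_intervals(x, level = conf.level)
  tibble::tibble(leaf_id = ci$leaf_id, subgroup = ci$path, n = ci$n,
                 estimate = ci$slope, std.error = ci$slope_se,
                 conf.low = ci$conf.low, conf.high = ci$conf.high)
}

#' Glance at a fitted PALM tree
#'
#' @param x A `"palm_tree"`.
#' @param ... Unused.
#' @return One-row tibble: `nobs`, `n.leaves`, `rss`, `n.iter`,
#'   `converged`.
#' @method glance palm_tree
#' @export
glance.palm_tree <- function(x, ...) {
  tibble::tibble(nobs = x$n, n.leaves = nrow(x$leaf_estimates),
                 rss = utils::tail(x$objective_trace, 1),
                 n.iter = x$n_iter, converged = x$converged)
}

#' Subgroup estimate table
#'
#' Formats the per-leaf estimates the way subgroup tables are reported:
#' estimate and 95% CI at two decimals, slope per unit decrease in the
#' support score.
#'
#' @param model A `"palm_tree"`.
#' @param digits Decimals for the printed columns.
#' @return Tibble with `subgroup`, `n`, `estimate`, `ci` (formatted
#'   string) plus the numeric columns.
#' @export
report_table <- function(model, digits = 2) {
  td <- tidy(model)
  dplyr::mutate(td,
    estimate_fmt = formatC(.data$estimate, format = "f", digits = digits),
    ci = sprintf("(%s, %s)",
                 formatC(.data$conf.low, format = "f", digits = digits),
                 formatC(.data$conf.high, format = "f", digits = digits)))
}

#' Slope estimate for a named demographic subgroup
#'
#' Returns the leaf slope for the subgroup defined by the given
#' demographic conditions. When the tree's leaves coincide with the
#' subgroup this is the leaf estimate itself; otherwise the
#' membership-weighted average of the leaf slopes over the subgroup's
#' members is returned (with a correspondingly pooled standard error).
#'
#' @param model A fitted `"palm_tree"`.
#' @param Z The modifier data frame used in the fit.
#' @param ... Named conditions, e.g. `education = c("low", "medium")`,
#'   `age_group = "60-72"`. Unnamed variables are unrestricted.
#' @return One-row tibble: `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `n`, `exact_leaf` (whether a single leaf contains
#'   exactly the subgroup members).
#' @export
subgroup_slope <- function(model, Z, ...) {
  stopifnot(inherits(model, "palm_tree"))
  Z <- as.data.frame(Z)
  cond <- list(...)
  sel <- rep(TRUE, nrow(Z))
  for (v in names(cond)) sel <- sel & as.character(Z[[v]]) %in% cond[[v]]
  if (!any(sel)) stop("no observations match the subgroup", call. = FALSE)
  leaf <- predict_leaf(model$tree, Z)
  est <- model$leaf_estimates
  tab <- table(leaf[sel])
  w <- as.numeric(tab) / sum(tab)
  ix <- match(as.integer(names(tab)), est$leaf_id)
  slope <- sum(w * est$slope[ix])
  # conservative pooling: weighted SEs, leaf estimates treated independent
  se <- sqrt(sum((w * est$slope_se[ix])^2))
  q <- stats::qnorm(0.975)
  tibble::tibble(estimate = slope, std.error = se,
                 conf.low = slope - q * se, conf.high = slope + q * se,
                 n = sum(sel),
                 exact_leaf = length(tab) == 1 &&
                   sum(leaf == as.integer(names(tab)[1])) == sum(sel))
}
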