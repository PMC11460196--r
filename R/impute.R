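#' Imputation plan for the cohort tables
#'
#' Chained-equations settings: number of completed datasets, iterations,
#' predictive-mean-matching donor count and seed. The visit sequence is
#' fixed to demographics (education, marital status), then phase-wise SSQ
#' items in phase order, then DASS items — predictors before outcomes.
#'
#' @param m Number of completed datasets.
#' @param n_iterations Chained passes over the incomplete variables.
#' @param pmm_donors Donor-pool size for predictive mean matching.
#' @param seed Seed for the imputation randomness.
#' @return A list of class `"imputation_plan"`.
#' @export
imputation_plan <- function(m = 1L, n_iterations = 10L, pmm_donors = 5L,
                            seed = 1L) {
  stopifnot(m >= 1, n_iterations >= 1, pmm_donors >= 1)
  structure(list(m = as.integer(m), n_iterations = as.integer(n_iterations),
                 pmm_donors = as.integer(pmm_donors), seed = as.integer(seed)),
            class = "imputation_plan")
}

#' Multivariate imputation by chained equations
#'
#' Iterative univariate conditional imputation for the cohort table:
#' education and marital status by multinomial-probability draws from a
#' fitted log-linear model; SSQ item counts and DASS items by predictive
#' mean matching (a seeded random donor among the `pmm_donors` observed
#' cases closest in predicted value), which keeps every imputed value in
#' its admissible range by construction. Phase-varying SSQ items use the
#' participant's mean over their other observed SSQ cells as a predictor
#' — a two-stage surrogate for a random-intercept repeated-measures
#' model. Observed cells are never altered.
#'
#' Participants with all 21 DASS items missing must be excluded first
#' (see [inclusion_filter()]).
#'
#' @param cohort Cohort tibble with `NA` marks.
#' @param plan An [imputation_plan()].
#' @return A list of `plan$m` completed cohort tibbles.
#' @export
impute_chained <- function(cohort, plan = imputation_plan()) {
  stopifnot(inherits(plan, "imputation_plan"))
  ssq_cols <- as.vector(sapply(1:5, function(p) paste0("ssq_p", p, "_i", 1:4)))
  dass_cols <- sprintf("dass_%02d", 1:21)
  cat_cols <- c("education", "marital")
  all_cols <- c(cat_cols, ssq_cols, dass_cols)
  missing_any <- vapply(all_cols, function(cl) anyNA(cohort[[cl]]), logical(1))
  if (anyNA(cohort$gender) || anyNA(cohort$age_group)) {
    stop("gender and age_group must be complete", call. = FALSE)
  }
  dm <- as.matrix(cohort[dass_cols])
  if (any(rowSums(!is.na(dm)) == 0)) {
    stop("cohort contains participants with a completely empty DASS-21; ",
         "apply inclusion_filter() first", call. = FALSE)
  }
  if (!any(missing_any)) return(replicate(plan$m, cohort, simplify = FALSE))

  obs_mask <- lapply(all_cols, function(cl) !is.na(cohort[[cl]]))
  names(obs_mask) <- all_cols
  for (cl in all_cols[missing_any]) {
    if (!any(obs_mask[[cl]])) {
      stop("no observed donors for variable '", cl, "'", call. = FALSE)
    }
  }

  out <- vector("list", plan$m)
  for (d in seq_len(plan$m)) {
    out[[d]] <- impute_once(cohort, plan, chain_seed = plan$seed + 7919L * (d - 1L),
                            ssq_cols = ssq_cols, dass_cols = dass_cols,
                            cat_cols = cat_cols, obs_mask = obs_mask,
                            missing_any = missing_any)
  }
  out
}

impute_once <- function(cohort, plan, chain_seed, ssq_cols, dass_cols,
                        cat_cols, obs_mask, missing_any) {
  set.seed(chain_seed)
  data <- cohort
  visit <- c(cat_cols, ssq_cols, dass_cols)
  visit <- visit[missing_any[visit]]

  # initialize missing cells by draws from the observed marginal
  for (cl in visit) {
    miss <- !obs_mask[[cl]]
    pool <- data[[cl]][obs_mask[[cl]]]
    data[[cl]][miss] <- sample(pool, sum(miss), replace = TRUE)
  }

  demo_mm <- function() {
    stats::model.matrix(~ gender + age_group + education + marital,
                        data = data)[, -1, drop = FALSE]
  }

  for (it in seq_len(plan$n_iterations)) {
    for (cl in visit) {
      miss <- !obs_mask[[cl]]
      if (cl %in% cat_cols) {
        other <- setdiff(cat_cols, cl)
        ssq_mean <- rowMeans(as.matrix(data[ssq_cols]))
        dass_mean <- rowMeans(as.matrix(data[dass_cols]))
        pred <- data.frame(gender = data$gender, age_group = data$age_group,
                           other = data[[other]], ssq_mean = ssq_mean,
                           dass_mean = dass_mean)
        yobs <- droplevels(data[[cl]][!miss])
        fit <- nnet::multinom(y ~ ., data = cbind(y = yobs, pred[!miss, ]),
                              trace = FALSE)
        pr <- stats::predict(fit, newdata = pred[miss, , drop = FALSE],
                             type = "probs")
        if (length(fit$lev) == 2) {
          pr <- cbind(1 - pr, pr)        # vector of P(second level) per row
        } else if (is.null(dim(pr))) {
          pr <- matrix(pr, nrow = 1)     # single missing row
        }
        lev <- fit$lev
        u <- stats::runif(sum(miss))
        cum <- pr %*% upper.tri(diag(ncol(pr)), diag = TRUE)
        pick <- max.col(cum >= u, ties.method = "first")
        data[[cl]][miss] <- factor(lev[pick], levels = levels(data[[cl]]))
      } else if (cl %in% ssq_cols) {
        others <- setdiff(ssq_cols, cl)
        om <- as.matrix(cohort[others])          # originally observed cells
        person_mean <- rowMeans(om, na.rm = TRUE)
        person_mean[is.nan(person_mean)] <- mean(om, na.rm = TRUE)
        X <- cbind(demo_mm(), person_mean = person_mean)
        data[[cl]] <- pmm_impute(data[[cl]], miss, X, plan$pmm_donors)
      } else {
        others <- setdiff(dass_cols, cl)
        om <- as.matrix(cohort[others])
        dass_pm <- rowMeans(om, na.rm = TRUE)
        dass_pm[is.nan(dass_pm)] <- mean(om, na.rm = TRUE)
        ssqn_now <- rowMeans(as.matrix(data[ssq_cols]))
        X <- cbind(demo_mm(), ssqn = ssqn_now, dass_pm = dass_pm)
        data[[cl]] <- pmm_impute(data[[cl]], miss, X, plan$pmm_donors)
      }
    }
  }
  data
}

# predictive mean matching: OLS on observed cases, nearest-donor draw
pmm_impute <- function(y, miss, X, k) {
  Xd <- cbind(1, X)
  fit <- stats::.lm.fit(Xd[!miss, , drop = FALSE], y[!miss])
  coef <- fit$coefficients
  coef[is.na(coef)] <- 0
  pred_obs <- as.vector(Xd[!miss, , drop = FALSE] %*% coef)
  pred_mis <- as.vector(Xd[miss, , drop = FALSE] %*% coef)
  y_obs <- y[!miss]
  ord <- order(pred_obs)
  po <- pred_obs[ord]
  yo <- y_obs[ord]
  n_obs <- length(po)
  k <- min(k, n_obs)
  pos <- findInterval(pred_mis, po)
  picks <- vapply(seq_along(pred_mis), function(i) {
    lo <- max(1L, pos[i] - k)
    hi <- min(n_obs, pos[i] + k)
    window <- lo:hi
    d <- abs(po[window] - pred_mis[i])
    donors <- window[order(d)][seq_len(min(k, length(window)))]
    yo[donors[sample.int(length(donors), 1L)]]
  }, numeric(1))
  y[miss] <- if (is.integer(y)) as.integer(picks) else picks
  y
}
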