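#' Inclusion filter: drop completely empty DASS-21 questionnaires
#'
#' Participants without a single DASS-21 answer cannot contribute to the
#' outcome and are removed before imputation; partial responders are
#' retained and later imputed.
#'
#' @param cohort Cohort tibble with `dass_01` ... `dass_21`.
#' @return The filtered cohort; the number of removed rows is reported
#'   via `message()` and recorded in the `"n_excluded"` attribute.
#' @export
inclusion_filter <- function(cohort) {
  dass_cols <- sprintf("dass_%02d", 1:21)
  dm <- as.matrix(cohort[dass_cols])
  empty <- rowSums(!is.na(dm)) == 0
  if (all(empty) && nrow(cohort) > 0) {
    warning("all participants have empty DASS-21 questionnaires", call. = FALSE)
  }
  message(sum(empty), " participant(s) excluded (empty DASS-21), ",
          sum(!empty), " retained")
  out <- cohort[!empty, , drop = FALSE]
  tr <- attr(cohort, "palmcohort_truth")
  if (!is.null(tr)) {
    attr(out, "palmcohort_truth") <- tr[!empty, , drop = FALSE]
  }
  attr(out, "n_excluded") <- sum(empty)
  out
}

#' Descriptive cohort summary
#'
#' Counts and percentages per demographic category (computed over
#' observed values) and median (IQR, linear-interpolation quantiles) for
#' the SSQN score and each DASS-21 dimension.
#'
#' @param scored A [score_cohort()] result.
#' @return Tibble with columns `characteristic`, `level`, `n`, `pct`,
#'   `median`, `q25`, `q75`.
#' @export
describe_cohort <- function(scored) {
  rows <- list()
  for (v in c("gender", "age_group", "marital", "education")) {
    if (!v %in% names(scored)) next
    tab <- table(scored[[v]])
    rows[[v]] <- tibble::tibble(
      characteristic = v, level = names(tab), n = as.integer(tab),
      pct = round(100 * as.integer(tab) / sum(tab)),
      median = NA_real_, q25 = NA_real_, q75 = NA_real_)
  }
  for (v in c("ssqn", "dass_general", "dass_depression", "dass_anxiety",
              "dass_stress")) {
    if (!v %in% names(scored)) next
    q <- stats::quantile(scored[[v]], c(0.25, 0.5, 0.75), type = 7)
    rows[[v]] <- tibble::tibble(
      characteristic = v, level = "median (IQR)", n = NA_integer_,
      pct = NA_real_, median = unname(q[2]), q25 = unname(q[1]),
      q75 = unname(q[3]))
  }
  dplyr::bind_rows(rows)
}

#' Share of zero scores per DASS-21 dimension
#'
#' @param scored A [score_cohort()] result.
#' @return Named numeric vector of percentages.
#' @export
zero_score_shares <- function(scored) {
  vapply(c(general = "dass_general", depression = "dass_depression",
           anxiety = "dass_anxiety", stress = "dass_stress"),
         function(cl) 100 * mean(scored[[cl]] == 0), numeric(1))
}

#' Run the full subgroup-discovery analysis
#'
#' Orchestrates the pipeline: generate the synthetic cohort, apply the
#' inclusion filter, impute missing values by chained equations, score
#' the scales, z-standardize, and fit one PALM tree per requested
#' outcome with the four sociodemographic variables as both candidate
#' effect modifiers and global adjustment covariates.
#'
#' @param config A [scenario_config()]; its seed drives generation.
#' @param outcomes Character subset of
#'   `c("general", "depression", "anxiety", "stress")`.
#' @param control A [palm_control()].
#' @param plan An [imputation_plan()]. With `m > 1`, leaf estimates are
#'   pooled across completed datasets of identical tree structure
#'   (averaged estimates, Rubin's rules for the variances); the fit on
#'   the first completed dataset is returned alongside.
#' @param norms Optional normative table for [score_cohort()]; default
#'   standardizes against the analysed population itself.
#' @param modifiers Candidate effect modifiers (column names).
#' @param globals Global adjustment covariates (column names).
#' @return List of class `"palm_analysis"`: `fits` (per outcome),
#'   `table` (combined tidy subgroup table), `descriptives`, `scored`,
#'   `cohort`, `n_excluded`.
#' @export
#' @examples
#' \donttest{
#' cfg <- scale_scenario(scenario_config(), 800)
#' res <- run_analysis(cfg, outcomes = "depression",
#'                     control = palm_control(n_mc = 500))
#' res$table
#' }
run_analysis <- function(config,
                         outcomes = c("general", "depression", "anxiety",
                                      "stress"),
                         control = palm_control(),
                         plan = imputation_plan(),
                         norms = NULL,
                         modifiers = c("gender", "age_group", "education",
                                       "marital"),
                         globals = c("gender", "age_group", "education",
                                     "marital")) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  stopifnot(length(outcomes) >= 1, length(modifiers) >= 1)
  cohort <- generate_cohort(config)
  included <- inclusion_filter(cohort)
  completed <- impute_chained(included, plan)
  scored_list <- lapply(completed, score_cohort, norms = norms)
  scored <- scored_list[[1]]

  fits <- list()
  tables <- list()
  for (out_name in outcomes) {
    per_dataset <- lapply(scored_list, function(sc) {
      y <- sc[[paste0("z_", out_name)]]
      x <- -(sc$ssqn - mean(sc$ssqn))
      fit_palm(y, x, G = sc[globals], Z = sc[modifiers], control = control)
    })
    fit <- per_dataset[[1]]
    td <- if (length(per_dataset) > 1) {
      pool_leaf_tables(lapply(per_dataset, tidy))
    } else {
      tidy(fit)
    }
    fits[[out_name]] <- fit
    tables[[out_name]] <- dplyr::mutate(td, outcome = out_name, .before = 1)
  }
  structure(list(fits = fits,
                 table = dplyr::bind_rows(tables),
                 descriptives = describe_cohort(scored),
                 zero_shares = zero_score_shares(scored),
                 scored = scored,
                 scored_list = scored_list,
                 cohort = cohort,
                 n_excluded = attr(included, "n_excluded"),
                 outcomes = outcomes),
            class = "palm_analysis")
}

# Rubin-style pooling over completed datasets sharing a leaf structure;
# falls back to the first dataset's table when structures disagree.
pool_leaf_tables <- function(tds) {
  sig <- vapply(tds, function(t) paste(t$subgroup, collapse = "|"), character(1))
  same <- sig == sig[1]
  if (!all(same)) {
    warning("tree structures differ across imputed datasets; ",
            "pooling the ", sum(same), " with the modal structure",
            call. = FALSE)
    tds <- tds[same]
  }
  m <- length(tds)
  est <- sapply(tds, function(t) t$estimate)
  se2 <- sapply(tds, function(t) t$std.error^2)
  if (is.null(dim(est))) { est <- matrix(est, nrow = 1); se2 <- matrix(se2, nrow = 1) }
  qbar <- rowMeans(est)
  ubar <- rowMeans(se2)
  b <- if (m > 1) apply(est, 1, stats::var) else 0
  tot <- sqrt(ubar + (1 + 1 / m) * b)
  q <- stats::qnorm(0.975)
  out <- tds[[1]]
  out$estimate <- qbar
  out$std.error <- tot
  out$conf.low <- qbar - q * tot
  out$conf.high <- qbar + q * tot
  out
}

#' @export
print.palm_analysis <- function(x, ...) {
  cat("PALM subgroup analysis of", length(x$fits), "outcome(s);",
      x$n_excluded, "participant(s) excluded by the inclusion filter\n\n")
  print(report_table_all(x))
  invisible(x)
}

#' Combined subgroup table across outcomes
#'
#' @param analysis A [run_analysis()] result.
#' @param digits Decimals for the formatted columns.
#' @return Tibble in the style of a published subgroup table.
#' @export
report_table_all <- function(analysis, digits = 2) {
  dplyr::mutate(
    analysis$table,
    estimate_fmt = formatC(.data$estimate, format = "f", digits = digits),
    ci = sprintf("(%s, %s)",
                 formatC(.data$conf.low, format = "f", digits = digits),
                 formatC(.data$conf.high, format = "f", digits = digits)))
}

#' Write / read the cohort CSV pair
#'
#' The cohort is externalized as two plain CSVs: a long SSQ table
#' (`participant_id`, `phase`, `item`, `count`) and a wide phase-5 table
#' (demographics plus `dass_01` ... `dass_21`). Missing values are empty
#' fields.
#'
#' @param cohort Cohort tibble.
#' @param dir Directory for `ssq_long.csv` and `phase5_wide.csv`.
#' @return `write_cohort()` the paths invisibly; `read_cohort()` the
#'   reassembled cohort tibble.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ssq_cols <- as.vector(sapply(1:5, function(p) paste0("ssq_p", p, "_i", 1:4)))
  long <- tidyr::pivot_longer(
    cohort[c("participant_id", ssq_cols)],
    dplyr::all_of(ssq_cols), names_to = "cell", values_to = "count")
  long$phase <- as.integer(sub("^ssq_p(\\d)_i\\d$", "\\1", long$cell))
  long$item <- as.integer(sub("^ssq_p\\d_i(\\d)$", "\\1", long$cell))
  long <- long[c("participant_id", "phase", "item", "count")]
  p1 <- file.path(dir, "ssq_long.csv")
  p2 <- file.path(dir, "phase5_wide.csv")
  utils::write.csv(long, p1, row.names = FALSE, na = "")
  wide_cols <- c("participant_id", "gender", "age_group", "marital",
                 "education", sprintf("dass_%02d", 1:21))
  utils::write.csv(cohort[intersect(wide_cols, names(cohort))], p2,
                   row.names = FALSE, na = "")
  invisible(c(ssq = p1, wide = p2))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  long <- utils::read.csv(file.path(dir, "ssq_long.csv"))
  wide <- utils::read.csv(file.path(dir, "phase5_wide.csv"))
  lv <- demographic_levels()
  for (v in names(lv)) wide[[v]] <- factor(wide[[v]], levels = lv[[v]])
  long$cell <- paste0("ssq_p", long$phase, "_i", long$item)
  ssq_wide <- tidyr::pivot_wider(long[c("participant_id", "cell", "count")],
                                 names_from = "cell", values_from = "count")
  out <- dplyr::left_join(tibble::as_tibble(wide), ssq_wide,
                          by = "participant_id")
  ssq_cols <- as.vector(sapply(1:5, function(p) paste0("ssq_p", p, "_i", 1:4)))
  dplyr::relocate(out, dplyr::all_of(ssq_cols), .after = "education")
}
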