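#' SSQN phase score
#'
#' Mean of the four SSQ item contact counts of one phase.
#'
#' @param items Numeric vector of four item counts in 0--6.
#' @return The phase score, a real in [0, 6].
#' @export
#' @examples
#' ssqn_phase_score(c(1, 2, 3, 2))
ssqn_phase_score <- function(items) {
  if (length(items) != 4) stop("a phase has exactly 4 SSQ items", call. = FALSE)
  if (anyNA(items)) {
    stop("missing SSQ item; imputation must precede scoring", call. = FALSE)
  }
  if (any(items < 0 | items > 6)) stop("SSQ counts must lie in 0..6", call. = FALSE)
  mean(items)
}

#' SSQN aggregate score
#'
#' Mean of the five phase scores.
#'
#' @param phase_scores Numeric vector of five phase scores.
#' @return The aggregate SSQN score.
#' @export
ssqn_aggregate <- function(phase_scores) {
  if (length(phase_scores) != 5) stop("expected 5 phase scores", call. = FALSE)
  if (anyNA(phase_scores)) {
    stop("missing phase score; imputation must precede scoring", call. = FALSE)
  }
  mean(phase_scores)
}

#' Standard DASS-21 item-to-dimension key
#'
#' The published assignment of the 21 items to the three subscales.
#'
#' @return Named list of three integer vectors of length 7.
#' @export
dass_default_key <- function() {
  list(
    depression = c(3L, 5L, 10L, 13L, 16L, 17L, 21L),
    anxiety = c(2L, 4L, 7L, 9L, 15L, 19L, 20L),
    stress = c(1L, 6L, 8L, 11L, 12L, 14L, 18L)
  )
}

check_dass_key <- function(key) {
  items <- sort(unlist(key, use.names = FALSE))
  if (!setequal(names(key), c("depression", "anxiety", "stress")) ||
      any(lengths(key) != 7) || !identical(items, 1:21)) {
    stop("DASS key must assign exactly 7 distinct items per dimension, ",
         "covering items 1..21", call. = FALSE)
  }
  key
}

#' DASS-21 subscale scores
#'
#' Doubled 7-item sums on the conventional 0--42 scale.
#'
#' @param items Integer vector of 21 item responses in 0--3.
#' @param key Item-to-dimension map, see [dass_default_key()].
#' @return Named numeric vector (depression, anxiety, stress).
#' @export
#' @examples
#' dass_subscales(rep(3, 21))
dass_subscales <- function(items, key = dass_default_key()) {
  check_dass_key(key)
  if (length(items) != 21) stop("expected 21 DASS items", call. = FALSE)
  if (anyNA(items)) {
    stop("missing DASS item; imputation must precede scoring", call. = FALSE)
  }
  if (any(items < 0 | items > 3)) stop("DASS items must lie in 0..3", call. = FALSE)
  vapply(key, function(ix) 2 * sum(items[ix]), numeric(1))
}

#' General-distress composite
#'
#' Mean of the three doubled subscale scores, an approximation of the
#' bifactor general factor (see the methods vignette).
#'
#' @param subscales Numeric vector of the three doubled subscale scores.
#' @return A real in [0, 42].
#' @export
general_distress <- function(subscales) {
  if (length(subscales) != 3) stop("expected 3 subscale scores", call. = FALSE)
  mean(subscales)
}

#' Z-standardization against a normative entry
#'
#' @param score Raw score(s).
#' @param mean,sd Normative mean and standard deviation (`sd > 0`).
#' @return `(score - mean) / sd`.
#' @export
standardize <- function(score, mean, sd) {
  if (!is.finite(sd) || sd <= 0) stop("normative SD must be > 0", call. = FALSE)
  (score - mean) / sd
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' `(k/(k-1)) * (1 - sum(item variances) / variance(item sums))`, using
#' the unbiased (n-1 denominator) variance throughout.
#'
#' @param item_matrix Complete numeric matrix, participants by items.
#' @return Alpha.
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (anyNA(m)) stop("item matrix must be complete", call. = FALSE)
  k <- ncol(m)
  if (k < 2 || nrow(m) < 2) stop("need >= 2 items and >= 2 observations", call. = FALSE)
  tot_var <- stats::var(rowSums(m))
  if (tot_var == 0) stop("zero total-score variance", call. = FALSE)
  (k / (k - 1)) * (1 - sum(apply(m, 2, stats::var)) / tot_var)
}

#' Item intercorrelation matrix
#'
#' @param item_matrix Complete numeric matrix, participants by items.
#' @return The k x k Pearson correlation matrix.
#' @export
item_intercorrelation <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (anyNA(m)) stop("item matrix must be complete", call. = FALSE)
  if (any(apply(m, 2, stats::sd) == 0)) {
    stop("constant item column", call. = FALSE)
  }
  stats::cor(m)
}

#' Score a completed cohort
#'
#' Computes per participant the phase-averaged SSQN score, the three
#' doubled DASS-21 subscales, the general-distress composite, and
#' z-standardized outcome scores.
#'
#' @param cohort Completed (no missing cells) cohort tibble with SSQ item
#'   columns `ssq_p*_i*` and DASS columns `dass_01` ... `dass_21`.
#' @param key DASS item key, see [dass_default_key()].
#' @param norms Normative table, a tibble with columns `dimension`
#'   (`depression`, `anxiety`, `stress`, `general`), `mean`, `sd`; or
#'   `NULL` (default) to standardize against the scored population's own
#'   mean/SD.
#' @return Tibble: `participant_id`, demographics, `ssqn`,
#'   `dass_depression`, `dass_anxiety`, `dass_stress`, `dass_general`,
#'   and `z_*` columns per dimension.
#' @export
score_cohort <- function(cohort, key = dass_default_key(), norms = NULL) {
  check_dass_key(key)
  ssq_cols <- as.vector(t(outer(1:5, 1:4, function(p, j)
    paste0("ssq_p", p, "_i", j))))
  dass_cols <- sprintf("dass_%02d", 1:21)
  need <- c(ssq_cols, dass_cols)
  if (!all(need %in% names(cohort))) {
    stop("cohort is missing item columns: ",
         paste(utils::head(setdiff(need, names(cohort)), 3), collapse = ", "),
         call. = FALSE)
  }
  sm <- as.matrix(cohort[ssq_cols])
  dm <- as.matrix(cohort[dass_cols])
  if (anyNA(sm) || anyNA(dm)) {
    stop("cohort contains missing items; impute before scoring", call. = FALSE)
  }
  phase <- sapply(1:5, function(p) rowMeans(sm[, paste0("ssq_p", p, "_i", 1:4),
                                               drop = FALSE]))
  out <- dplyr::select(cohort, dplyr::any_of(
    c("participant_id", "gender", "age_group", "marital", "education")))
  out$ssqn <- rowMeans(phase)
  for (dim_name in names(key)) {
    out[[paste0("dass_", dim_name)]] <-
      2 * rowSums(dm[, key[[dim_name]], drop = FALSE])
  }
  out$dass_general <- (out$dass_depression + out$dass_anxiety +
                         out$dass_stress) / 3
  for (dim_name in c("depression", "anxiety", "stress", "general")) {
    raw <- out[[paste0("dass_", dim_name)]]
    if (is.null(norms)) {
      nm_mean <- mean(raw); nm_sd <- stats::sd(raw)
    } else {
      row <- norms[norms$dimension == dim_name, ]
      if (nrow(row) != 1) stop("norms must have one row per dimension", call. = FALSE)
      nm_mean <- row$mean; nm_sd <- row$sd
    }
    out[[paste0("z_", dim_name)]] <- standardize(raw, nm_mean, nm_sd)
  }
  out
}
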