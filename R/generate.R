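#' Generate cohort demographics with exact marginals
#'
#' Assigns gender, age group, marital status and education to
#' `n_included + n_empty_dass` participants. The included block realizes
#' the configured category counts exactly (each variable is an
#' independently permuted block vector, so attributes are mutually
#' independent); the extra empty-DASS participants draw their demographics
#' proportionally to the marginals.
#'
#' @param config A [scenario_config()].
#' @return A tibble with `participant_id` and the four demographic
#'   factors. The attribute `"palmcohort_truth"` records which rows are
#'   designated empty-DASS participants.
#' @export
generate_demographics <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  lv <- demographic_levels()
  n_inc <- config$n_included
  n_tot <- n_inc + config$n_empty_dass
  set.seed(config$seed)

  cols <- lapply(names(lv), function(v) {
    marg <- config$demographic_marginals[[v]][lv[[v]]]
    base <- rep(names(marg), times = marg)
    inc <- sample(base, n_inc)           # independent permutation per variable
    extra <- if (config$n_empty_dass > 0) {
      sample(names(marg), config$n_empty_dass, replace = TRUE,
             prob = marg / sum(marg))
    } else character(0)
    factor(c(inc, extra), levels = lv[[v]])
  })
  names(cols) <- names(lv)

  empty <- c(rep(FALSE, n_inc), rep(TRUE, config$n_empty_dass))
  ord <- sample.int(n_tot)               # interleave empty-DASS rows
  out <- tibble::tibble(
    participant_id = seq_len(n_tot),
    gender = cols$gender[ord],
    age_group = cols$age_group[ord],
    marital = cols$marital[ord],
    education = cols$education[ord]
  )
  attr(out, "palmcohort_truth") <- tibble::tibble(
    participant_id = out$participant_id,
    empty_dass = empty[ord]
  )
  out
}

#' Generate SSQ item counts for five phases
#'
#' One-factor ordinal model: each participant carries a latent support
#' trait shared across phases with the configured phase correlation; each
#' phase/item latent value is `loading * trait + residual`, discretized
#' through the ordered thresholds into contact counts 0--6 (four items
#' per phase, phases 1--5).
#'
#' @param config A [scenario_config()].
#' @param demographics Output of [generate_demographics()].
#' @return The input tibble with 20 added columns `ssq_p<phase>_i<item>`;
#'   the truth attribute gains `true_ssqn`, the pre-missingness
#'   phase-averaged SSQN score.
#' @export
generate_ssq <- function(config, demographics) {
  stopifnot(inherits(config, "scenario_config"))
  n <- nrow(demographics)
  lam <- config$ssq_loading
  rho <- config$phase_correlation
  tau <- config$ssq_thresholds
  set.seed(config$seed + 1L)

  u <- stats::rnorm(n)
  out <- demographics
  item_cols <- list()
  for (p in 1:5) {
    u_p <- sqrt(rho) * u + sqrt(1 - rho) * stats::rnorm(n)
    for (j in 1:4) {
      x <- lam * u_p + sqrt(1 - lam^2) * stats::rnorm(n)
      item_cols[[paste0("ssq_p", p, "_i", j)]] <- findInterval(x, tau)
    }
  }
  out <- dplyr::bind_cols(out, tibble::as_tibble(item_cols))
  tr <- truth_of(demographics)
  tr$true_ssqn <- rowMeans(as.matrix(tibble::as_tibble(item_cols)))
  attr(out, "palmcohort_truth") <- tr
  out
}

#' Generate DASS-21 item responses with planted subgroup effects
#'
#' For each subscale (depression, anxiety, stress) a latent z-score is
#' drawn as `subgroup intercept + planted slope * (mean(SSQN) - SSQN) +
#' global effects + Gaussian noise` (a configurable fraction of the noise
#' is shared across subscales, acting as a common distress component).
#' The z-score maps to a raw doubled subscale score through the
#' configured norm mean/SD, rounded to the nearest even integer and
#' clipped to [0, 42], and the raw score is allocated uniformly at random
#' over all admissible 7-item response vectors (items 0--3 whose doubled
#' sum equals the score).
#'
#' @param config A [scenario_config()].
#' @param demographics Demographic tibble (with SSQ columns allowed).
#' @param true_ssqn Pre-missingness phase-averaged SSQN per participant;
#'   defaults to the truth recorded by [generate_ssq()].
#' @param round_items If `FALSE`, skip the even-rounding/item-allocation
#'   stage and store the continuous raw subscale scores in columns
#'   `raw_<dimension>` instead (used by exact plant-recovery checks).
#' @return The input tibble with columns `dass_01` ... `dass_21` (or raw
#'   score columns); the truth attribute gains the latent z-scores and
#'   subgroup labels per dimension.
#' @export
generate_dass <- function(config, demographics, true_ssqn = NULL,
                          round_items = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  n <- nrow(demographics)
  tr <- truth_of(demographics)
  if (is.null(true_ssqn)) {
    if (is.null(tr$true_ssqn)) {
      stop("true_ssqn not supplied and not found in the cohort truth; ",
           "run generate_ssq() first", call. = FALSE)
    }
    true_ssqn <- tr$true_ssqn
  }
  set.seed(config$seed + 2L)

  d <- mean(true_ssqn) - true_ssqn     # per unit *decrease* in support
  glob <- rep(0, n)
  if (nrow(config$global_effects) > 0) {
    for (k in seq_len(nrow(config$global_effects))) {
      ge <- config$global_effects[k, ]
      glob <- glob + ge$shift * (as.character(demographics[[ge$variable]]) == ge$level)
    }
  }
  kappa <- config$noise_shared
  g_noise <- stats::rnorm(n)
  key <- dass_default_key()
  corr <- if (round_items) slope_correction(config) else NULL

  out <- demographics
  item_mat <- matrix(NA_integer_, n, 21)
  for (dim_name in c("depression", "anxiety", "stress")) {
    ps <- config$planted_slopes[config$planted_slopes$outcome == dim_name, ]
    slope <- rep(NA_real_, n)
    inter <- rep(NA_real_, n)
    lab <- rep(NA_character_, n)
    unmatched <- rep(TRUE, n)
    for (j in seq_len(nrow(ps))) {
      m <- matches_subgroup_vec(ps[j, ], demographics)
      if (any(m & !unmatched)) {
        stop("planted subgroups for '", dim_name, "' overlap", call. = FALSE)
      }
      slope[m] <- if (is.null(corr)) ps$slope[j] else {
        ps$slope[j] / corr[[dim_name]][ps$label[j]]
      }
      inter[m] <- ps$intercept[j]
      lab[m] <- ps$label[j]
      unmatched <- unmatched & !m
    }
    if (any(unmatched)) {
      stop("subgroup lookup failed for ", sum(unmatched), " participants in '",
           dim_name, "' (partition violated)", call. = FALSE)
    }
    eps <- sqrt(kappa) * g_noise + sqrt(1 - kappa) * stats::rnorm(n)
    z <- inter + slope * d + glob + config$noise_sd * eps
    nm <- config$dass_norms[config$dass_norms$dimension == dim_name, ]
    raw <- nm$mean + nm$sd * z
    tr[[paste0("z_", dim_name)]] <- z
    tr[[paste0("subgroup_", dim_name)]] <- lab
    if (round_items) {
      raw_even <- pmin(42, pmax(0, 2 * floor(raw / 2 + 0.5)))
      items <- allocate_items(raw_even / 2)
      item_mat[, key[[dim_name]]] <- items
    } else {
      out[[paste0("raw_", dim_name)]] <- raw
    }
  }
  if (round_items) {
    colnames(item_mat) <- sprintf("dass_%02d", 1:21)
    out <- dplyr::bind_cols(out, tibble::as_tibble(item_mat))
  }
  attr(out, "palmcohort_truth") <- tr
  out
}

# First-order correction for the floor-at-zero distortion of the raw
# scale. Clipping a latent Gaussian score at 0 shrinks both the raw-scale
# regression slope (by the average clip derivative, Phi((m - 1)/s)) and
# the raw-scale SD; after standardization by the realized SD the
# recoverable slope is planted * derivative / sd_ratio. The generator
# divides the latent slope by this factor so that the planted value is
# what ordinary least squares on the scored data recovers. All terms are
# closed-form functions of the configuration (cell weights from the
# marginals, cell means from the subgroup intercepts).
slope_correction <- function(config) {
  marg <- config$demographic_marginals
  w_of <- function(v) marg[[v]] / sum(marg[[v]])
  cells <- expand.grid(gender = names(w_of("gender")),
                       age_group = names(w_of("age_group")),
                       education = names(w_of("education")),
                       stringsAsFactors = FALSE)
  w <- w_of("gender")[cells$gender] * w_of("age_group")[cells$age_group] *
    w_of("education")[cells$education]
  out <- list()
  for (dim_name in c("depression", "anxiety", "stress")) {
    ps <- config$planted_slopes[config$planted_slopes$outcome == dim_name, ]
    nm <- config$dass_norms[config$dass_norms$dimension == dim_name, ]
    member <- sapply(seq_len(nrow(ps)), function(j)
      matches_subgroup_vec(ps[j, ], cells))
    m_cell <- nm$mean + nm$sd * as.vector(member %*% ps$intercept)
    s <- nm$sd * config$noise_sd
    # realized SD of the clipped mixture vs the latent SD
    a <- m_cell / s
    ey <- m_cell * stats::pnorm(a) + s * stats::dnorm(a)
    ey2 <- (m_cell^2 + s^2) * stats::pnorm(a) + m_cell * s * stats::dnorm(a)
    var_clip <- sum(w * ey2) - sum(w * ey)^2
    var_lat <- sum(w * m_cell^2) - sum(w * m_cell)^2 + s^2
    sd_ratio <- sqrt(var_clip / var_lat)
    deriv_cell <- stats::pnorm((m_cell - 1) / s)
    fac <- vapply(seq_len(nrow(ps)), function(j) {
      idx <- member[, j]
      sum(w[idx] * deriv_cell[idx]) / sum(w[idx]) / sd_ratio
    }, numeric(1))
    out[[dim_name]] <- stats::setNames(fac, ps$label)
  }
  out
}

# Uniform allocation of a 7-item sum s (0..21) to items 0..3, by
# sequential conditional sampling from the composition-count table.
allocate_items <- function(s) {
  counts <- composition_counts()       # counts[r + 1, s + 1]
  n <- length(s)
  rem <- as.integer(s)
  items <- matrix(0L, n, 7)
  for (t in 1:7) {
    r_left <- 7 - t
    w <- sapply(0:3, function(v) {
      ok <- rem - v >= 0 & rem - v <= 3 * r_left
      out <- numeric(n)
      out[ok] <- counts[r_left + 1, rem[ok] - v + 1]
      out
    })
    if (n == 1) w <- matrix(w, nrow = 1)
    cum <- w %*% upper.tri(diag(4), diag = TRUE)
    u <- stats::runif(n) * cum[, 4]
    items[, t] <- max.col(cum >= u, ties.method = "first") - 1L
    rem <- rem - items[, t]
  }
  items
}

# counts[r + 1, s + 1] = number of vectors of r items in 0..3 summing to s
composition_counts <- function() {
  counts <- matrix(0, 8, 22)
  counts[1, 1] <- 1
  for (r in 1:7) {
    for (s in 0:(3 * r)) {
      v <- 0:min(3, s)
      counts[r + 1, s + 1] <- sum(counts[r, s - v + 1])
    }
  }
  counts
}

matches_subgroup_vec <- function(row, demographics) {
  m <- rep(TRUE, nrow(demographics))
  for (v in c("gender", "age_group", "education")) {
    spec <- row[[v]]
    if (!identical(spec, "*")) {
      m <- m & as.character(demographics[[v]]) %in%
        strsplit(spec, ",", fixed = TRUE)[[1]]
    }
  }
  m
}

#' Apply the missingness mechanism
#'
#' Masks, in order: the designated empty-DASS participants (all 21 items),
#' a configured number of partial DASS responders (a random nonempty
#' proper subset of items), whole SSQ phase blocks at age-dependent rates
#' (missing at random: probabilities depend on observed demographics,
#' never on the masked values), and education/marital status at their
#' configured rates.
#'
#' @param config A [scenario_config()].
#' @param cohort Complete cohort tibble from [generate_dass()].
#' @return The cohort with `NA` marks; observed cells are untouched.
#' @export
apply_missingness <- function(config, cohort) {
  stopifnot(inherits(config, "scenario_config"))
  n <- nrow(cohort)
  tr <- truth_of(cohort)
  empty <- tr$empty_dass %||% rep(FALSE, n)
  if (sum(empty) != config$n_empty_dass) {
    stop("cohort truth designates ", sum(empty), " empty-DASS participants, ",
         "config expects ", config$n_empty_dass, call. = FALSE)
  }
  if (config$n_partial_dass > n - sum(empty)) {
    stop("n_partial_dass exceeds the number of non-empty participants",
         call. = FALSE)
  }
  set.seed(config$seed + 3L)
  out <- cohort
  dass_cols <- sprintf("dass_%02d", 1:21)

  for (cl in dass_cols) out[[cl]][empty] <- NA_integer_

  partial_ids <- sample(which(!empty), config$n_partial_dass)
  n_miss <- pmin(20L, 1L + stats::rbinom(length(partial_ids), 19, 0.08))
  for (i in seq_along(partial_ids)) {
    miss_items <- sample(21L, n_miss[i])
    for (cl in dass_cols[miss_items]) out[[cl]][partial_ids[i]] <- NA_integer_
  }

  rate <- config$missing_rates$ssq_phase[as.character(cohort$age_group)]
  for (p in 1:5) {
    block <- stats::runif(n) < rate
    for (j in 1:4) out[[paste0("ssq_p", p, "_i", j)]][block] <- NA_integer_
  }

  mask_ed <- stats::runif(n) < config$missing_rates$education
  out$education[mask_ed] <- NA
  mask_ma <- stats::runif(n) < config$missing_rates$marital
  out$marital[mask_ma] <- NA
  attr(out, "palmcohort_truth") <- tr
  out
}

#' Generate a full synthetic cohort
#'
#' Chains [generate_demographics()], [generate_ssq()], [generate_dass()]
#' and [apply_missingness()].
#'
#' @param config A [scenario_config()].
#' @param missingness Apply the missingness stage (default `TRUE`).
#' @return Cohort tibble; the `"palmcohort_truth"` attribute (see
#'   [cohort_truth()]) records the generating latent quantities.
#' @export
#' @examples
#' cfg <- scale_scenario(scenario_config(), 400)
#' cohort <- generate_cohort(cfg)
#' dim(cohort)
generate_cohort <- function(config, missingness = TRUE) {
  out <- generate_demographics(config)
  out <- generate_ssq(config, out)
  out <- generate_dass(config, out)
  if (missingness) out <- apply_missingness(config, out)
  out
}

#' Retrieve the generator truth of a synthetic cohort
#'
#' @param cohort A tibble produced by the generator functions.
#' @return A tibble with per-participant latent quantities (true SSQN,
#'   latent z-scores, planted subgroup labels, empty-DASS designation).
#' @export
cohort_truth <- function(cohort) {
  tr <- attr(cohort, "palmcohort_truth")
  if (is.null(tr)) stop("cohort carries no generator truth", call. = FALSE)
  tr
}

truth_of <- function(cohort) {
  attr(cohort, "palmcohort_truth") %||%
    tibble::tibble(participant_id = cohort$participant_id)
}
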