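#' Scenario configuration for the synthetic retiree cohort
#'
#' A scenario bundles every parameter of the synthetic cohort generator:
#' sample sizes, exact demographic marginals, the one-factor ordinal model
#' for the four Social Support Questionnaire (SSQ) items over five survey
#' phases, the planted subgroup-specific associations between the SSQN
#' support score and the DASS-21 outcome dimensions, global additive
#' covariate effects, and the missingness mechanism.
#'
#' The default scenario is calibrated once so that the generated cohort
#' reproduces the published descriptive summaries of the Helsinki retiree
#' cohort it emulates: exact categorical marginals (e.g. 3,627 women of
#' 4,466 included participants), SSQN median 1.50 with IQR (1.15, 2.05),
#' SSQ Cronbach's alpha of about 0.90, a general-distress composite with
#' median near 5.7 and mean near 6.0, a depression zero-score share near
#' 22.9%, and subgroup slope/intercept structure matching the published
#' subgroup table and tree figure.
#'
#' @param n_included Number of participants with at least one DASS-21
#'   answer (the analysis sample).
#' @param n_empty_dass Number of extra generated participants whose DASS-21
#'   questionnaire is completely empty; they exercise the inclusion filter.
#' @param n_partial_dass Number of included participants with a nonempty
#'   proper subset of DASS-21 items missing.
#' @param demographic_marginals Named list of named integer vectors; per
#'   variable the category counts, each summing to `n_included`.
#' @param ssq_loading Common loading of the four SSQ items on the
#'   phase-level latent support trait, in (0, 1).
#' @param ssq_thresholds Strictly increasing cutpoints on the latent scale
#'   that discretize item values into counts 0--6.
#' @param phase_correlation Within-person correlation of the latent support
#'   trait across survey phases, in (0, 1).
#' @param planted_slopes Tibble with columns `outcome`, `label`, `gender`,
#'   `age_group`, `education` (level sets as comma-joined strings, `"*"`
#'   meaning any), `slope` (z-score change per unit decrease in SSQN) and
#'   `intercept` (z-scale subgroup level). Per outcome the subgroups must
#'   partition the demographic space.
#' @param global_effects Tibble with columns `variable`, `level`, `shift`:
#'   additive z-scale shifts applied to every outcome.
#' @param dass_norms Tibble with columns `dimension`, `mean`, `sd`: the
#'   raw-scale location/scale used to map latent z-scores to doubled
#'   DASS-21 subscale scores.
#' @param noise_sd Standard deviation of the Gaussian outcome noise on the
#'   z scale.
#' @param noise_shared Fraction of the noise variance shared across the
#'   three subscales (a common distress component), in [0, 1).
#' @param missing_rates List with elements `ssq_phase` (named per age
#'   group: per-phase probability that a whole 4-item SSQ block is
#'   missing), `education` and `marital` (scalar rates).
#' @param seed Integer seed driving all generator randomness.
#'
#' @return A list of class `"scenario_config"`.
#' @export
#' @examples
#' cfg <- scenario_config()
#' cfg$n_included
scenario_config <- function(n_included = 4466L,
                            n_empty_dass = 57L,
                            n_partial_dass = 296L,
                            demographic_marginals = default_marginals(),
                            ssq_loading = 0.87,
                            ssq_thresholds = default_ssq_thresholds(),
                            phase_correlation = 0.6,
                            planted_slopes = default_planted_slopes(),
                            global_effects = default_global_effects(),
                            dass_norms = default_dass_norms(),
                            noise_sd = 1,
                            noise_shared = 0.5,
                            missing_rates = default_missing_rates(),
                            seed = 1L) {
  cfg <- list(
    n_included = as.integer(n_included),
    n_empty_dass = as.integer(n_empty_dass),
    n_partial_dass = as.integer(n_partial_dass),
    demographic_marginals = demographic_marginals,
    ssq_loading = ssq_loading,
    ssq_thresholds = ssq_thresholds,
    phase_correlation = phase_correlation,
    planted_slopes = planted_slopes,
    global_effects = global_effects,
    dass_norms = dass_norms,
    noise_sd = noise_sd,
    noise_shared = noise_shared,
    missing_rates = missing_rates,
    seed = as.integer(seed)
  )
  class(cfg) <- "scenario_config"
  validate_scenario(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat("  n_included:", x$n_included,
      " (+", x$n_empty_dass, "empty-DASS )\n")
  cat("  seed:", x$seed, "\n")
  cat("  outcomes planted:",
      paste(unique(x$planted_slopes$outcome), collapse = ", "), "\n")
  invisible(x)
}

# Demographic level sets used throughout the package.
demographic_levels <- function() {
  list(
    gender = c("women", "men"),
    age_group = c("60-72", "73-82"),
    marital = c("married", "divorced", "unmarried"),
    education = c("low", "medium", "high")
  )
}

# Complete-data marginals. Gender and age are complete in the published
# descriptives; marital/education counts there are observed (2% / 1%
# missing) and are rescaled proportionally to the full n = 4,466.
#' Complete-data demographic marginals of the default scenario
#'
#' @return The default component, see [scenario_config()].
#' @export
default_marginals <- function() {
  list(
    gender = c(women = 3627L, men = 839L),
    age_group = c("60-72" = 2477L, "73-82" = 1989L),
    marital = c(married = 2576L, divorced = 1423L, unmarried = 467L),
    education = c(low = 1762L, medium = 1371L, high = 1333L)
  )
}

# Cutpoints on the standard-normal latent scale mapping to item counts
# 0..6; calibrated against SSQN median 1.50, IQR (1.15, 2.05) and the
# right-skewed item frequencies of the short SSQ form.
#' Calibrated latent-scale thresholds for the SSQ items
#'
#' @return The default component, see [scenario_config()].
#' @export
default_ssq_thresholds <- function() {
  c(-1.064, 0.007, 1.000, 1.920, 2.772, 3.561)
}

# Raw-scale location/scale per DASS-21 dimension used by the generator to
# map latent z to doubled subscale scores. Calibrated jointly with the
# subgroup intercepts against the published medians and zero-shares.
#' Calibrated raw-scale norms for the DASS-21 subscales
#'
#' @return The default component, see [scenario_config()].
#' @export
default_dass_norms <- function() {
  tibble::tibble(
    dimension = c("depression", "anxiety", "stress"),
    mean = c(4.85, 4.72, 6.85),
    sd = c(5.20, 4.82, 6.75)
  )
}

#' Planted subgroup structure of the default scenario
#'
#' One row per (outcome, subgroup); subgroups per outcome partition the
#' demographic space. Slopes are the published subgroup estimates
#' (z-score change per unit decrease in SSQN); intercepts are z-scale
#' subgroup levels chosen by calibration so that each outcome's fitted
#' tree reproduces the published split structure (gender first for
#' depression and stress, age first for anxiety, education first for the
#' general-distress composite).
#'
#' @return A tibble with columns `outcome`, `label`, `gender`,
#'   `age_group`, `education`, `slope`, `intercept`.
#' @export
default_planted_slopes <- function() {
  tribble_ps <- function(...) {
    m <- matrix(c(...), ncol = 7, byrow = TRUE)
    tibble::tibble(
      outcome = m[, 1], label = m[, 2], gender = m[, 3],
      age_group = m[, 4], education = m[, 5],
      slope = as.numeric(m[, 6]), intercept = as.numeric(m[, 7])
    )
  }
  tribble_ps(
    "depression", "Men, low education", "men", "*", "low", 0.17, -0.255,
    "depression", "Men, medium and high education", "men", "*", "medium,high", 0.08, -0.505,
    "depression", "Women, low education", "women", "*", "low", 0.12, 0.276,
    "depression", "Women, medium and high education", "women", "*", "medium,high", 0.20, -0.024,
    "anxiety", "60-72 years, low and medium education", "*", "60-72", "low,medium", 0.14, 0.239,
    "anxiety", "60-72 years, high education", "*", "60-72", "high", 0.10, 0.039,
    "anxiety", "73-82 years, low education", "*", "73-82", "low", 0.20, -0.102,
    "anxiety", "73-82 years, medium and high education", "*", "73-82", "medium,high", 0.12, -0.302,
    "stress", "Men, 60-72 years", "men", "60-72", "*", 0.13, 0.340,
    "stress", "Men, 73-82 years", "men", "73-82", "*", 0.23, 0.640,
    "stress", "Women, low education", "women", "*", "low", 0.13, 0.058,
    "stress", "Women, medium and high education", "women", "*", "medium,high", 0.16, -0.220
  )
}

# Small additive z-shifts for covariates not carrying planted subgroup
# structure; recovered by the PALM global coefficients.
#' Default global additive covariate effects
#'
#' @return The default component, see [scenario_config()].
#' @export
default_global_effects <- function() {
  tibble::tibble(
    variable = c("marital", "marital"),
    level = c("divorced", "unmarried"),
    shift = c(0.10, 0.10)
  )
}

# Per-phase probability that a whole 4-item SSQ block is missing, by age
# group (a missing-at-random mechanism: older participants skip more).
# Marginally 1 - (1 - p)^5 ~ 24.7% of participants have any missing SSQ.
#' Default missingness rates
#'
#' @return The default component, see [scenario_config()].
#' @export
default_missing_rates <- function() {
  list(
    ssq_phase = c("60-72" = 0.048, "73-82" = 0.064),
    education = 0.01,
    marital = 0.02
  )
}

validate_scenario <- function(cfg) {
  lv <- demographic_levels()
  if (!setequal(names(cfg$demographic_marginals), names(lv))) {
    stop("demographic_marginals must cover gender, age_group, marital, education",
         call. = FALSE)
  }
  for (v in names(lv)) {
    marg <- cfg$demographic_marginals[[v]]
    if (!setequal(names(marg), lv[[v]])) {
      stop("marginals for '", v, "' must be named with levels: ",
           paste(lv[[v]], collapse = ", "), call. = FALSE)
    }
    if (any(marg < 0)) stop("negative marginal count for '", v, "'", call. = FALSE)
    if (sum(marg) != cfg$n_included) {
      stop("marginals for '", v, "' sum to ", sum(marg),
           ", expected n_included = ", cfg$n_included, call. = FALSE)
    }
  }
  if (cfg$ssq_loading <= 0 || cfg$ssq_loading >= 1) {
    stop("ssq_loading must lie in (0, 1)", call. = FALSE)
  }
  if (any(diff(cfg$ssq_thresholds) <= 0)) {
    stop("ssq_thresholds must be strictly increasing", call. = FALSE)
  }
  if (cfg$phase_correlation <= 0 || cfg$phase_correlation >= 1) {
    stop("phase_correlation must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (cfg$noise_shared < 0 || cfg$noise_shared >= 1) {
    stop("noise_shared must lie in [0, 1)", call. = FALSE)
  }
  rates <- c(cfg$missing_rates$ssq_phase, cfg$missing_rates$education,
             cfg$missing_rates$marital)
  if (any(rates < 0 | rates > 1)) {
    stop("missing rates must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_partial_dass + cfg$n_empty_dass >
      cfg$n_included + cfg$n_empty_dass) {
    stop("requested missing DASS counts exceed cohort size", call. = FALSE)
  }
  check_partition(cfg$planted_slopes)
  if (any(cfg$dass_norms$sd <= 0)) stop("dass_norms sd must be > 0", call. = FALSE)
  cfg
}

# Every demographic cell must match exactly one planted subgroup per
# outcome; anything else is a configuration error.
check_partition <- function(planted) {
  lv <- demographic_levels()
  cells <- expand.grid(gender = lv$gender, age_group = lv$age_group,
                       education = lv$education, stringsAsFactors = FALSE)
  for (out in unique(planted$outcome)) {
    rows <- planted[planted$outcome == out, ]
    hits <- vapply(seq_len(nrow(cells)), function(i) {
      sum(vapply(seq_len(nrow(rows)), function(j) {
        subgroup_matches(rows[j, ], cells[i, ]) }, logical(1)))
    }, integer(1))
    if (any(hits != 1L)) {
      bad <- cells[hits != 1L, , drop = FALSE][1, ]
      stop("planted subgroups for '", out, "' do not partition the ",
           "demographic space (cell ", paste(unlist(bad), collapse = "/"),
           " matched ", hits[hits != 1L][1], " subgroups)", call. = FALSE)
    }
  }
  invisible(planted)
}

subgroup_matches <- function(row, cell) {
  ok <- TRUE
  for (v in c("gender", "age_group", "education")) {
    spec <- row[[v]]
    if (!identical(spec, "*")) {
      ok <- ok && cell[[v]] %in% strsplit(spec, ",", fixed = TRUE)[[1]]
    }
  }
  ok
}

#' Scale a scenario down to a smaller cohort
#'
#' Rescales the demographic marginals (largest-remainder rounding so each
#' variable still sums exactly to the new size) and the empty/partial DASS
#' counts proportionally, keeping every distributional parameter fixed.
#' Used for reduced-size replication studies.
#'
#' @param config A [scenario_config()].
#' @param n_included New analysis-sample size.
#' @return A `scenario_config` of the requested size.
#' @export
scale_scenario <- function(config, n_included) {
  stopifnot(inherits(config, "scenario_config"), n_included >= 20)
  f <- n_included / config$n_included
  marg <- lapply(config$demographic_marginals, function(m) {
    scaled <- m * f
    base <- floor(scaled)
    short <- n_included - sum(base)
    if (short > 0) {
      idx <- order(scaled - base, decreasing = TRUE)[seq_len(short)]
      base[idx] <- base[idx] + 1
    }
    stats::setNames(as.integer(base), names(m))
  })
  config$n_included <- as.integer(n_included)
  config$demographic_marginals <- marg
  config$n_empty_dass <- as.integer(round(config$n_empty_dass * f))
  config$n_partial_dass <- as.integer(round(config$n_partial_dass * f))
  validate_scenario(config)
}

#' Write / read a scenario configuration as JSON
#'
#' Serializes every field of a [scenario_config()] so a scenario can be
#' versioned alongside the analysis and re-read reproducibly.
#'
#' @param config A [scenario_config()].
#' @param path File path for the JSON document.
#' @return `write_scenario()` the path invisibly; `read_scenario()` a
#'   validated `scenario_config`.
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  payload <- unclass(config)
  # named atomic vectors must become JSON objects, not bare arrays
  payload$demographic_marginals <- lapply(payload$demographic_marginals,
                                          as.list)
  payload$missing_rates$ssq_phase <- as.list(payload$missing_rates$ssq_phase)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  marg <- lapply(raw$demographic_marginals, function(m)
    stats::setNames(as.integer(unlist(m)), names(m)))
  mr <- raw$missing_rates
  scenario_config(
    n_included = raw$n_included,
    n_empty_dass = raw$n_empty_dass,
    n_partial_dass = raw$n_partial_dass,
    demographic_marginals = marg,
    ssq_loading = raw$ssq_loading,
    ssq_thresholds = raw$ssq_thresholds,
    phase_correlation = raw$phase_correlation,
    planted_slopes = tibble::as_tibble(raw$planted_slopes),
    global_effects = tibble::as_tibble(raw$global_effects),
    dass_norms = tibble::as_tibble(raw$dass_norms),
    noise_sd = raw$noise_sd,
    noise_shared = raw$noise_shared,
    missing_rates = list(
      ssq_phase = stats::setNames(as.numeric(unlist(mr$ssq_phase)),
                                  names(mr$ssq_phase)),
      education = mr$education,
      marital = mr$marital),
    seed = raw$seed
  )
}
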