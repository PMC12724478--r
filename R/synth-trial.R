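# Synthetic three-arm feedback-trial generator with known ground-truth arm
# effects, used to validate the whole costing -> outcomes -> imputation -> CEA
# chain against parameters that are known by construction.

.arm_levels <- c("no_feedback", "nontailored", "tailored")

.direct_categories <- c(
  "inpatient", "outpatient_physician", "outpatient_psychotherapist",
  "outpatient_nonphysician", "formal_nursing", "informal_care", "medication"
)

# Follow-up category cost moments of the reference (no-feedback) arm; the
# gamma shape (mean/sd)^2 < 1 reproduces the strong right skew of health-care
# cost data (SD well above the mean in every category).
.ref_cost_mean <- c(950, 611, 321, 169, 61, 439, 309)
.ref_cost_sd   <- c(4223, 1359, 880, 543, 923, 2429, 3167)
.ref_indirect_mean <- 1776
.ref_indirect_sd   <- 4312

# Variables eligible for missing-at-random masking. Randomisation arm, id,
# baseline PHQ-9 (the stratification variable) and the covariates that drive
# the MAR mechanism (age, gender) are never masked.
.miss_eligible <- c(
  "scid", "phq_t2", "phq_t3", "eq5d_t0", "eq5d_t3", "vas_t0", "vas_t3",
  paste0("q_post_", .direct_categories), "absence_pre", "absence_post"
)

.flag_cols <- c("in_base", "in_primary", "in_extended")

#' Simulation configuration for a synthetic three-arm trial
#'
#' Defaults emulate a three-arm randomised trial of automated feedback after
#' internet-based depression screening: 343/338/331 participants per arm,
#' right-skewed six-month costs (baseline total mean 4528, SD 10,734 euro),
#' EQ-5D-5L utility index 0.69 (SD 0.25) at baseline, PHQ-9 14.77 (SD 4.00)
#' truncated at the inclusion threshold of 10, a 180-day follow-up, and
#' missing-at-random masking of about 9% of cells within eligible variables
#' (about 4.3% of all data cells).
#'
#' @param arm_sizes Integer vector of three arm sizes, named after the arms
#'   (no_feedback, nontailored, tailored).
#' @param true_cost_shift Ground-truth shift of expected follow-up total cost
#'   (euro) of the two feedback arms relative to the no-feedback arm.
#' @param true_qaly_shift Ground-truth shift of expected QALYs of the two
#'   feedback arms relative to the no-feedback arm.
#' @param cost_mean,cost_sd Follow-up cost mean/SD (euro) per direct-cost
#'   category in the reference arm; gamma shapes are `(mean/sd)^2`.
#' @param indirect_mean,indirect_sd Follow-up indirect (productivity-loss)
#'   cost moments in the reference arm (euro).
#' @param baseline_cost_mean Expected pre-period total cost (euro); category
#'   composition is the reference composition rescaled.
#' @param eq5d_mean,eq5d_sd Baseline utility-index moments (truncated to the
#'   value-set range \[-0.661, 1\]).
#' @param vas_mean,vas_sd Baseline EQ VAS moments (truncated to \[0, 100\]).
#' @param phq_mean,phq_sd Baseline PHQ-9 moments (truncated to \[10, 27\],
#'   the screened-positive range).
#' @param phq_drift_t2,phq_drift_t3 Mean PHQ-9 change at the 1-month and
#'   6-month follow-up common to all arms.
#' @param phq_arm_drift Additional mean PHQ-9 change at T3 in the two
#'   feedback arms (half of it applies at T2).
#' @param phq_noise_sd SD of PHQ-9 measurement noise at follow-up.
#' @param followup_days Planned follow-up horizon in days.
#' @param daily_wage Gross daily wage (euro) used to convert absence days to
#'   indirect costs and back.
#' @param miss_rate_overall Target fraction of missing cells over all data
#'   columns.
#' @param miss_rate_variable Target missing fraction within each eligible
#'   variable; if `NULL` it is derived from `miss_rate_overall`.
#' @param extended_extra Number of additional participants flagged as part of
#'   the extended sample only (re-included after exclusion).
#' @param n_primary Size of the nested primary-analysis sample selector.
#' @param seed Integer seed; a fixed seed reproduces the table exactly.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(arm_sizes = c(no_feedback = 343, nontailored = 338, tailored = 331),
                       true_cost_shift = c(nontailored = 372, tailored = -597),
                       true_qaly_shift = c(nontailored = -0.002, tailored = -0.006),
                       cost_mean = .ref_cost_mean,
                       cost_sd = .ref_cost_sd,
                       indirect_mean = .ref_indirect_mean,
                       indirect_sd = .ref_indirect_sd,
                       baseline_cost_mean = 4528,
                       eq5d_mean = 0.69, eq5d_sd = 0.25,
                       vas_mean = 57.44, vas_sd = 21.93,
                       phq_mean = 14.77, phq_sd = 4.00,
                       phq_drift_t2 = -1.7, phq_drift_t3 = -4.1,
                       phq_arm_drift = c(nontailored = -0.1, tailored = -0.8),
                       phq_noise_sd = 4.5,
                       followup_days = 180,
                       daily_wage = 150,
                       miss_rate_overall = 0.043,
                       miss_rate_variable = 0.09,
                       extended_extra = 0,
                       n_primary = NULL,
                       seed = 1L) {
  cfg <- list(
    arm_sizes = arm_sizes, true_cost_shift = true_cost_shift,
    true_qaly_shift = true_qaly_shift, cost_mean = cost_mean, cost_sd = cost_sd,
    indirect_mean = indirect_mean, indirect_sd = indirect_sd,
    baseline_cost_mean = baseline_cost_mean,
    eq5d_mean = eq5d_mean, eq5d_sd = eq5d_sd,
    vas_mean = vas_mean, vas_sd = vas_sd,
    phq_mean = phq_mean, phq_sd = phq_sd,
    phq_drift_t2 = phq_drift_t2, phq_drift_t3 = phq_drift_t3,
    phq_arm_drift = phq_arm_drift, phq_noise_sd = phq_noise_sd,
    followup_days = followup_days, daily_wage = daily_wage,
    miss_rate_overall = miss_rate_overall,
    miss_rate_variable = miss_rate_variable,
    extended_extra = extended_extra,
    n_primary = n_primary, seed = seed
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid sim_config field '%s': %s", field, msg), call. = FALSE)
  }
  if (length(cfg$arm_sizes) != 3 || any(!is.finite(cfg$arm_sizes)) ||
      any(cfg$arm_sizes < 2) || any(cfg$arm_sizes != round(cfg$arm_sizes)))
    fail("arm_sizes", "three integers, each >= 2")
  if (length(cfg$true_cost_shift) != 2 || any(!is.finite(cfg$true_cost_shift)))
    fail("true_cost_shift", "two finite shifts (nontailored, tailored)")
  if (length(cfg$true_qaly_shift) != 2 || any(!is.finite(cfg$true_qaly_shift)))
    fail("true_qaly_shift", "two finite shifts (nontailored, tailored)")
  if (length(cfg$cost_mean) != 7 || any(cfg$cost_mean < 0))
    fail("cost_mean", "seven nonnegative category means")
  if (length(cfg$cost_sd) != 7 || any(cfg$cost_sd <= 0))
    fail("cost_sd", "seven positive category SDs")
  if (cfg$indirect_mean < 0) fail("indirect_mean", "must be >= 0")
  if (cfg$indirect_sd <= 0) fail("indirect_sd", "must be > 0")
  if (cfg$baseline_cost_mean < 0) fail("baseline_cost_mean", "must be >= 0")
  if (cfg$followup_days <= 0) fail("followup_days", "must be > 0")
  if (cfg$daily_wage < 0) fail("daily_wage", "must be >= 0")
  for (f in c("miss_rate_overall", "miss_rate_variable")) {
    r <- cfg[[f]]
    if (!is.null(r) && (!is.finite(r) || r < 0 || r >= 1))
      fail(f, "must lie in [0, 1)")
  }
  if (cfg$extended_extra < 0 || cfg$extended_extra != round(cfg$extended_extra))
    fail("extended_extra", "nonnegative integer")
  n <- sum(cfg$arm_sizes)
  if (!is.null(cfg$n_primary) &&
      (cfg$n_primary < 2 || cfg$n_primary > n))
    fail("n_primary", sprintf("must lie in [2, %d]", n))
  if (!is.null(cfg$seed) && (!is.finite(cfg$seed) || abs(cfg$seed) >= 2^31))
    fail("seed", "a 32-bit integer")
  invisible(cfg)
}

# truncated-normal sampler (inverse-CDF; exact, vectorised)
rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# nominal mean whose truncated-normal mean equals `target` on [lo, hi], so
# configured baseline moments are realised moments, not pre-truncation ones
.tnorm_nominal <- function(target, sd, lo, hi) {
  tmean <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  stats::uniroot(function(mu) tmean(mu) - target,
                 interval = c(lo - 5 * sd, hi + 5 * sd), tol = 1e-8)$root
}

#' Generate a complete synthetic trial table
#'
#' Draws a missingness-free participant-level table with the configured arm
#' sizes, baseline marginals, right-skewed per-category resource costs
#' (converted to resource-use quantities via the default unit-cost table) and
#' arm-specific ground-truth shifts applied to follow-up costs and T3
#' outcomes. A fixed seed reproduces the table exactly.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` (the trial table), with the config echoed in
#'   attribute `"sim_config"`.
#' @export
generate_trial <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_base <- sum(config$arm_sizes)
  n <- n_base + config$extended_extra
  arm <- factor(c(rep(.arm_levels, times = config$arm_sizes),
                  rep(.arm_levels, length.out = config$extended_extra)),
                levels = .arm_levels)

  # per-arm expected shifts: costs scale multiplicatively so every category
  # keeps its gamma shape; QALY shifts act on the T3 utility index (a QALY
  # shift d over a 180-day horizon corresponds to a 4*d index shift at T3)
  total_ref <- sum(config$cost_mean) + config$indirect_mean
  cost_shift <- c(no_feedback = 0, config$true_cost_shift)[as.character(arm)]
  qaly_shift <- c(no_feedback = 0, config$true_qaly_shift)[as.character(arm)]
  cost_factor <- 1 + cost_shift / total_ref

  gender <- factor(sample(c("woman", "man", "nonbinary"), n, replace = TRUE,
                          prob = c(0.708, 0.284, 0.008)),
                   levels = c("woman", "man", "nonbinary"))
  age <- round(rtnorm(n, 37.5, 14.09, 18, 79), 1)
  city_size <- factor(sample(c("small", "medium", "large"), n, replace = TRUE,
                             prob = c(0.35, 0.30, 0.35)),
                      levels = c("small", "medium", "large"))
  insurance <- factor(sample(c("statutory", "private"), n, replace = TRUE,
                             prob = c(0.92, 0.08)),
                      levels = c("statutory", "private"))
  scid <- stats::rbinom(n, 1, 0.55)
  self_belief <- stats::rbinom(n, 1, 0.62)

  phq_t0 <- round(rtnorm(n, .tnorm_nominal(config$phq_mean, config$phq_sd, 10, 27),
                         config$phq_sd, 10, 27))
  arm_drift <- c(no_feedback = 0, config$phq_arm_drift)[as.character(arm)]
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  phq_t2 <- clip(round(phq_t0 + config$phq_drift_t2 + 0.5 * arm_drift +
                         stats::rnorm(n, 0, config$phq_noise_sd)), 0, 27)
  phq_t3 <- clip(round(phq_t0 + config$phq_drift_t3 + arm_drift +
                         stats::rnorm(n, 0, config$phq_noise_sd)), 0, 27)
  day_t2 <- 30L + sample(-7:7, n, replace = TRUE)
  day_t3 <- config$followup_days + sample(-14:14, n, replace = TRUE)

  eq5d_t0 <- rtnorm(n, .tnorm_nominal(config$eq5d_mean, config$eq5d_sd, -0.661, 1),
                    config$eq5d_sd, -0.661, 1)
  # mean improvement of ~0.08 index points over follow-up; clipping at 1
  # reproduces the ceiling effect of utility-index data. The configured QALY
  # shift enters as a 4x index shift at T3 (180-day horizon), inflated by
  # ~1.08 to offset first-order ceiling attenuation of the arm contrast.
  eq5d_t3 <- clip(config$eq5d_mean + 0.10 + 4.3 * qaly_shift +
                    0.5 * (eq5d_t0 - config$eq5d_mean) +
                    stats::rnorm(n, 0, 0.20), -0.661, 1)
  vas_t0 <- round(rtnorm(n, .tnorm_nominal(config$vas_mean, config$vas_sd, 0, 100),
                         config$vas_sd, 0, 100), 0)
  vas_t3 <- clip(round(0.5 * vas_t0 + 33 + 430 * qaly_shift +
                         stats::rnorm(n, 0, 16)), 0, 100)

  uc <- default_unit_costs()
  unit <- stats::setNames(uc$unit_cost, uc$category)[.direct_categories]
  shape <- (config$cost_mean / config$cost_sd)^2
  pre_scale <- config$baseline_cost_mean / total_ref

  q <- list()
  for (k in seq_along(.direct_categories)) {
    cat_k <- .direct_categories[k]
    mean_pre <- config$cost_mean[k] * pre_scale
    cost_pre <- if (mean_pre > 0)
      stats::rgamma(n, shape[k], scale = mean_pre / shape[k]) else numeric(n)
    mean_post <- config$cost_mean[k] * cost_factor
    cost_post <- if (config$cost_mean[k] > 0)
      stats::rgamma(n, shape[k], scale = mean_post / shape[k]) else numeric(n)
    q[[paste0("q_pre_", cat_k)]] <- cost_pre / unit[[cat_k]]
    q[[paste0("q_post_", cat_k)]] <- cost_post / unit[[cat_k]]
  }
  ind_shape <- (config$indirect_mean / config$indirect_sd)^2
  absence_pre <- stats::rgamma(n, ind_shape,
    scale = config$indirect_mean * pre_scale / ind_shape) / config$daily_wage
  absence_post <- stats::rgamma(n, ind_shape,
    scale = config$indirect_mean * cost_factor / ind_shape) / config$daily_wage

  in_base <- c(rep(TRUE, n_base), rep(FALSE, config$extended_extra))
  n_primary <- if (is.null(config$n_primary))
    round(n_base * 965 / 1012) else config$n_primary
  in_primary <- rep(FALSE, n)
  in_primary[sample(which(in_base), min(n_primary, n_base))] <- TRUE

  tab <- data.frame(
    id = seq_len(n), arm = arm, gender = gender, age = age,
    city_size = city_size, insurance = insurance, scid = scid,
    self_belief = self_belief,
    phq_t0 = phq_t0, phq_t2 = phq_t2, phq_t3 = phq_t3,
    day_t2 = day_t2, day_t3 = day_t3,
    eq5d_t0 = eq5d_t0, eq5d_t3 = eq5d_t3,
    vas_t0 = vas_t0, vas_t3 = vas_t3,
    absence_pre = absence_pre, absence_post = absence_post,
    stringsAsFactors = FALSE
  )
  tab <- cbind(tab, as.data.frame(q))
  tab$in_base <- in_base
  tab$in_primary <- in_primary
  tab$in_extended <- TRUE
  attr(tab, "sim_config") <- config
  tab
}

#' Echo the configured ground-truth arm effects
#'
#' @param config A [sim_config()] object.
#' @return Data frame with one row per feedback arm: true expected follow-up
#'   cost difference and QALY difference versus the no-feedback arm.
#' @export
true_values <- function(config = sim_config()) {
  validate_sim_config(config)
  data.frame(
    arm = c("nontailored", "tailored"),
    delta_cost = unname(config$true_cost_shift),
    delta_qaly = unname(config$true_qaly_shift)
  )
}

#' Mask cells missing-at-random
#'
#' Sets cells of the eligible follow-up variables to `NA` under a MAR
#' mechanism whose missingness probability depends only on always-observed
#' covariates (arm, age, gender). Arm, id, baseline PHQ-9 and the MAR
#' covariates are never masked. With the default per-variable rate of 9% the
#' realised overall fraction over all data columns is about 4.3%.
#'
#' @param table A complete trial table from [generate_trial()].
#' @param config A [sim_config()]; `miss_rate_variable` is the per-variable
#'   target rate (derived from `miss_rate_overall` when `NULL`).
#' @return The table with `NA`s inserted.
#' @export
apply_missingness <- function(table, config = sim_config()) {
  validate_sim_config(config)
  rate <- config$miss_rate_variable
  eligible <- intersect(.miss_eligible, names(table))
  if (is.null(rate)) {
    n_data_cols <- sum(!names(table) %in% .flag_cols)
    rate <- config$miss_rate_overall * n_data_cols / length(eligible)
  }
  if (rate >= 1) stop("missingness rate must be < 1", call. = FALSE)
  if (rate == 0 || length(eligible) == 0) return(table)
  set.seed(config$seed + 777L)

  # MAR linear predictor from always-observed covariates only
  lp <- 0.015 * (table$age - mean(table$age)) +
    0.25 * (table$gender == "woman") +
    0.20 * (table$arm == "tailored")
  # per-variable intercept calibrated so the mean masking probability hits
  # the target rate exactly in expectation
  alpha <- stats::uniroot(
    function(a) mean(stats::plogis(a + lp)) - rate,
    interval = c(-20, 20), tol = 1e-10
  )$root
  p <- stats::plogis(alpha + lp)
  for (v in eligible) {
    table[[v]][stats::runif(nrow(table)) < p] <- NA
  }
  table
}

#' Write / read a trial table as delimited text with a sidecar manifest
#'
#' The table is written tab-delimited with a header row; a JSON sidecar
#' (`<path>.meta.json`) records the column dictionary (types and factor
#' levels), the seed and an echo of the simulation config so a read-back
#' restores types exactly.
#'
#' @param table Trial table.
#' @param path Output file path.
#' @return `write_trial_table` returns `path` invisibly; `read_trial_table`
#'   returns the restored `data.frame`.
#' @export
write_trial_table <- function(table, path) {
  cfg <- attr(table, "sim_config")
  meta <- list(
    columns = lapply(table, function(col) {
      if (is.factor(col)) list(type = "factor", levels = levels(col))
      else list(type = class(col)[1])
    }),
    seed = if (!is.null(cfg)) cfg$seed else NULL,
    sim_config = if (!is.null(cfg)) unclass(cfg) else NULL
  )
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", na.strings = "NA",
                           stringsAsFactors = FALSE, check.names = FALSE)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    for (v in names(meta$columns)) {
      spec <- meta$columns[[v]]
      if (identical(spec$type, "factor") && v %in% names(tab))
        tab[[v]] <- factor(tab[[v]], levels = unlist(spec$levels))
      if (identical(spec$type, "logical") && v %in% names(tab))
        tab[[v]] <- as.logical(tab[[v]])
    }
  } else {
    for (v in intersect(c("arm", "gender", "city_size", "insurance"), names(tab)))
      tab[[v]] <- factor(tab[[v]])
  }
  tab
}
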