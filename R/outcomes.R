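# Effect measures: EQ-5D-5L index scoring against a value set, QALYs under a
# linear-trend interpolation between baseline and 6-month follow-up, EQ VAS
# QALYs, PHQ-9 severity bands, and depression-free days from an exactly
# integrated piecewise-linear PHQ-9 trajectory.

.eq5d_dims <- c("mobility", "self_care", "usual_activities",
                "pain_discomfort", "anxiety_depression")
.phq_bands <- c("minimal", "mild", "moderate", "moderately severe", "severe")

#' Read an EQ-5D-5L value set from delimited text
#'
#' Two dialects are auto-detected from the header. Long form: columns
#' `profile` (five-digit string such as "11221") and `index`, one row per
#' health state. Coefficient form: columns `dimension`, `level`, `decrement`
#' giving an additive decrement per dimension-level (level 1 = no decrement);
#' the index of a profile is `1 - sum(decrements)`.
#'
#' @param path Delimited text file (tab or comma separated) with a header.
#' @return An object of class `value_set` with fields `type`, `ceiling`,
#'   `floor` and either `lookup` (long) or `coef` (5 x 5 decrement matrix).
#' @export
read_value_set <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  if (all(c("profile", "index") %in% names(tab))) {
    lookup <- stats::setNames(tab$index, sprintf("%05d", as.integer(tab$profile)))
    vs <- list(type = "lookup", lookup = lookup,
               ceiling = unname(lookup["11111"]),
               floor = min(lookup))
  } else if (all(c("dimension", "level", "decrement") %in% names(tab))) {
    coef <- matrix(0, nrow = 5, ncol = 5,
                   dimnames = list(.eq5d_dims, paste0("L", 1:5)))
    dim_idx <- match(tab$dimension, .eq5d_dims)
    if (anyNA(dim_idx))
      stop("unknown dimension in value set: ",
           paste(unique(tab$dimension[is.na(dim_idx)]), collapse = ", "),
           call. = FALSE)
    coef[cbind(dim_idx, tab$level)] <- tab$decrement
    vs <- list(type = "additive", coef = coef, ceiling = 1,
               floor = 1 - sum(coef[, 5]))
  } else {
    stop("value set must have columns (profile, index) or ",
         "(dimension, level, decrement)", call. = FALSE)
  }
  class(vs) <- "value_set"
  vs
}

#' Score EQ-5D-5L profiles with a value set
#'
#' @param profile Integer vector of the five dimension levels (1--5), or an
#'   n x 5 matrix of profiles (rows = respondents).
#' @param value_set A [read_value_set()] object.
#' @return Utility index value(s), guaranteed within the value set's
#'   `[floor, ceiling]`.
#' @export
score_eq5d <- function(profile, value_set) {
  if (!inherits(value_set, "value_set"))
    stop("value_set must be a 'value_set' object", call. = FALSE)
  prof <- if (is.matrix(profile)) profile else matrix(profile, nrow = 1)
  if (ncol(prof) != 5)
    stop("a profile has exactly 5 dimension levels", call. = FALSE)
  if (any(!prof %in% 1:5))
    stop("dimension levels must be integers in 1..5", call. = FALSE)
  if (value_set$type == "lookup") {
    key <- apply(prof, 1, paste0, collapse = "")
    idx <- value_set$lookup[key]
    if (anyNA(idx))
      stop("profile absent from value set: ",
           paste(unique(key[is.na(idx)]), collapse = ", "), call. = FALSE)
    unname(idx)
  } else {
    dec <- vapply(seq_len(nrow(prof)), function(i)
      sum(value_set$coef[cbind(1:5, prof[i, ])]), numeric(1))
    value_set$ceiling - dec
  }
}

#' QALYs from utility indices under a linear trend
#'
#' Over a 180-day horizon with a linear change in utility between baseline
#' (T0) and follow-up (T3), the quality-adjusted life years accrued are
#' \deqn{QALY = [I_{T0} + \frac{I_{T3}-I_{T0}}{2}\cdot\frac{180}{\Delta d}]\cdot\frac{1}{2}}
#' where \eqn{\Delta d} is the observed number of days between the two
#' assessments; the slope is rescaled to the 180-day horizon and the final
#' factor 1/2 converts the half-year to years. When \eqn{\Delta d = 180}
#' this is the mean of the two indices times 0.5. No discounting is applied.
#'
#' @param index_t0,index_t3 Utility indices at baseline and follow-up.
#' @param delta_days Positive days elapsed between the two assessments;
#'   values outside \[90, 365\] are flagged with a warning.
#' @return QALYs (years).
#' @export
qaly_index <- function(index_t0, index_t3, delta_days) {
  if (any(delta_days <= 0, na.rm = TRUE))
    stop("delta_days must be > 0", call. = FALSE)
  extreme <- !is.na(delta_days) & (delta_days < 90 | delta_days > 365)
  if (any(extreme))
    warning(sum(extreme), " follow-up interval(s) outside [90, 365] days")
  (index_t0 + (index_t3 - index_t0) / 2 * (180 / delta_days)) * 0.5
}

#' QALYs from the EQ VAS
#'
#' Applies the same linear-trend QALY construction to the visual analogue
#' scale rescaled to \[0, 1\] (VAS / 100).
#'
#' @param vas_t0,vas_t3 EQ VAS ratings in \[0, 100\].
#' @param delta_days Positive days between the assessments.
#' @return QALYs (years).
#' @export
qaly_vas <- function(vas_t0, vas_t3, delta_days) {
  for (v in list(vas_t0, vas_t3))
    if (any(v < 0 | v > 100, na.rm = TRUE))
      stop("EQ VAS scores must lie in [0, 100]", call. = FALSE)
  qaly_index(vas_t0 / 100, vas_t3 / 100, delta_days)
}

#' PHQ-9 severity band
#'
#' Maps a PHQ-9 total score to the five standard severity bands:
#' minimal (0--4), mild (5--9), moderate (10--14), moderately severe
#' (15--19), severe (20--27).
#'
#' @param score PHQ-9 total score(s) in \[0, 27\].
#' @return Factor with levels minimal < mild < moderate < moderately severe
#'   < severe; `NA` scores propagate.
#' @export
phq_severity_band <- function(score) {
  if (any(score < 0 | score > 27, na.rm = TRUE))
    stop("PHQ-9 scores must lie in [0, 27]", call. = FALSE)
  cut(score, breaks = c(-Inf, 4, 9, 14, 19, Inf), labels = .phq_bands,
      ordered_result = TRUE)
}

# measure of {t in [t_a, t_b] : v(t) < thr} for the linear segment through
# (t_a, v_a), (t_b, v_b); exact via the single threshold crossing
.segment_below <- function(t_a, t_b, v_a, v_b, thr) {
  len <- t_b - t_a
  if (len <= 0) return(0)
  if (v_a < thr && v_b < thr) return(len)
  if (v_a >= thr && v_b >= thr) return(0)
  t_star <- (thr - v_a) / (v_b - v_a) * len
  if (v_a < thr) t_star else len - t_star
}

# integral over [t_a, t_b] of clamp((upper - v(t)) / (upper - lower), 0, 1):
# split at the lower/upper crossings, then each piece is linear (trapezoid)
.segment_credit <- function(t_a, t_b, v_a, v_b, lower, upper) {
  len <- t_b - t_a
  if (len <= 0) return(0)
  ts <- c(0, len)
  if (v_b != v_a) {
    for (thr in c(lower, upper)) {
      t_star <- (thr - v_a) / (v_b - v_a) * len
      if (t_star > 0 && t_star < len) ts <- c(ts, t_star)
    }
  }
  ts <- sort(unique(ts))
  credit <- function(t) {
    v <- v_a + (v_b - v_a) * t / len
    pmin(pmax((upper - v) / (upper - lower), 0), 1)
  }
  sum(vapply(seq_len(length(ts) - 1), function(i) {
    (credit(ts[i]) + credit(ts[i + 1])) / 2 * (ts[i + 1] - ts[i])
  }, numeric(1)))
}

#' Depression-free days from a PHQ-9 trajectory
#'
#' The PHQ-9 trajectory through the three assessments (T0 at day 0, T2 and
#' T3 at their day offsets) is taken to be piecewise linear; beyond T3 the
#' last observed score is carried forward (so DFD stays monotone in each
#' score), and the trajectory is truncated at the `horizon` (default 180
#' days). Depression-free days (DFD) are computed exactly from the segment
#' threshold crossings, not by day sampling.
#'
#' Under the binary rule a day is depression-free iff the interpolated score
#' is strictly below `threshold` (default 5, the minimal-severity band).
#' Under the graded rule a day earns partial credit
#' `clamp((upper - score)/(upper - lower), 0, 1)`, integrated exactly.
#'
#' @param scores Length-3 numeric (PHQ-9 at T0, T2, T3), each in \[0, 27\].
#' @param day_offsets Length-2 numeric: days of T2 and T3 after T0, strictly
#'   increasing and positive.
#' @param rule `"binary"` or `"graded"`.
#' @param threshold Binary-rule threshold (score strictly below = free).
#' @param lower,upper Graded-rule full-credit and zero-credit scores.
#' @param horizon Evaluation horizon in days.
#' @return DFD in \[0, horizon\]; `NA` if any score or offset is `NA`.
#' @export
depression_free_days <- function(scores, day_offsets, rule = c("binary", "graded"),
                                 threshold = 5, lower = 5, upper = 10,
                                 horizon = 180) {
  rule <- match.arg(rule)
  if (anyNA(scores) || anyNA(day_offsets)) return(NA_real_)
  if (length(scores) != 3 || length(day_offsets) != 2)
    stop("need 3 scores (T0, T2, T3) and 2 day offsets (T2, T3)", call. = FALSE)
  if (any(scores < 0 | scores > 27))
    stop("PHQ-9 scores must lie in [0, 27]", call. = FALSE)
  d <- c(0, day_offsets)
  if (any(diff(d) <= 0))
    stop("day offsets must be strictly increasing and positive", call. = FALSE)
  v <- as.numeric(scores)
  # extend/truncate the trajectory to the fixed horizon
  if (d[3] < horizon) {
    d <- c(d, horizon)
    v <- c(v, v[3])     # carry the last score forward
  } else if (d[3] > horizon) {
    for (i in 2:3) {
      if (d[i] >= horizon) {
        frac <- (horizon - d[i - 1]) / (d[i] - d[i - 1])
        v <- c(v[seq_len(i - 1)], v[i - 1] + frac * (v[i] - v[i - 1]))
        d <- c(d[seq_len(i - 1)], horizon)
        break
      }
    }
  }
  total <- 0
  for (i in seq_len(length(d) - 1)) {
    total <- total + if (rule == "binary")
      .segment_below(d[i], d[i + 1], v[i], v[i + 1], threshold)
    else
      .segment_credit(d[i], d[i + 1], v[i], v[i + 1], lower, upper)
  }
  total
}

#' Construct the per-participant outcome set for a trial table
#'
#' Computes QALYs from the utility index, VAS QALYs, depression-free days
#' and PHQ-9 severity bands at baseline and follow-up.
#'
#' @param table Trial table with `eq5d_t0`, `eq5d_t3`, `vas_t0`, `vas_t3`,
#'   `phq_t0`, `phq_t2`, `phq_t3`, `day_t2`, `day_t3` columns.
#' @param dfd_rule,dfd_threshold,dfd_lower,dfd_upper See
#'   [depression_free_days()].
#' @param horizon DFD horizon in days.
#' @return Data frame: `qaly`, `qaly_vas`, `dfd`, `severity_t0`,
#'   `severity_t3`.
#' @export
compute_outcomes <- function(table, dfd_rule = "binary", dfd_threshold = 5,
                             dfd_lower = 5, dfd_upper = 10, horizon = 180) {
  qaly <- qaly_index(table$eq5d_t0, table$eq5d_t3, table$day_t3)
  qvas <- qaly_vas(table$vas_t0, table$vas_t3, table$day_t3)
  dfd <- vapply(seq_len(nrow(table)), function(i) {
    depression_free_days(
      c(table$phq_t0[i], table$phq_t2[i], table$phq_t3[i]),
      c(table$day_t2[i], table$day_t3[i]),
      rule = dfd_rule, threshold = dfd_threshold,
      lower = dfd_lower, upper = dfd_upper, horizon = horizon
    )
  }, numeric(1))
  data.frame(
    qaly = qaly, qaly_vas = qvas, dfd = dfd,
    severity_t0 = phq_severity_band(table$phq_t0),
    severity_t3 = phq_severity_band(table$phq_t3)
  )
}
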