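# Economic-evaluation core: pairwise incremental costs/effects pooled over
# imputations, ICERs with dominance classification on the cost-effectiveness
# plane, monetary net-benefit regression, CEACs over a willingness-to-pay
# grid, sensitivity scenarios, subgroup curves and baseline balance tests.

.base_wtp_grid <- seq(0, 160000, by = 10000)   # euro per QALY, 17 points
.dfd_wtp_grid  <- seq(0, 200, by = 10)         # euro per DFD
.dfd_wtp_anchor <- 15                          # euro per DFD (9% of income)

#' Pairwise comparisons of a three-arm trial
#'
#' @return List of `c(intervention, comparator)` pairs: each feedback arm
#'   versus no feedback, and tailored versus nontailored.
#' @export
default_comparisons <- function() {
  list(
    nontailored_vs_no_feedback = c("nontailored", "no_feedback"),
    tailored_vs_no_feedback = c("tailored", "no_feedback"),
    tailored_vs_nontailored = c("tailored", "nontailored")
  )
}

# difference in arm means of `y` (ig - cg) with its OLS-on-dummy variance;
# closed form identical to lm(y ~ arm_indicator)
.diff_in_means <- function(y, is_ig) {
  n1 <- sum(is_ig); n0 <- sum(!is_ig)
  if (n1 < 2 || n0 < 2)
    stop("each compared arm needs >= 2 participants", call. = FALSE)
  m1 <- mean(y[is_ig]); m0 <- mean(y[!is_ig])
  rss <- sum((y[is_ig] - m1)^2) + sum((y[!is_ig] - m0)^2)
  s2 <- rss / (n1 + n0 - 2)
  list(coef = m1 - m0, var = s2 * (1 / n1 + 1 / n0), df = n1 + n0 - 2)
}

# rows of `tab` belonging to the comparison, in order (ig flag, subset)
.comparison_subset <- function(tab, comparison) {
  keep <- tab$arm %in% comparison
  if (!all(comparison %in% tab$arm))
    stop("arm(s) absent from data: ",
         paste(setdiff(comparison, unique(tab$arm)), collapse = ", "),
         call. = FALSE)
  list(tab = tab[keep, , drop = FALSE],
       is_ig = tab$arm[keep] == comparison[1])
}

#' Pooled incremental cost and effect for one pairwise comparison
#'
#' Per completed dataset, the incremental cost and effect are the
#' difference-in-means OLS coefficients on the arm indicator; estimates and
#' variances are pooled with Rubin's rules. Two-sided p-values come from the
#' pooled t reference.
#'
#' @param imps An `imputation_set` whose tables carry the analysis columns
#'   (see [prepare_analysis()]), or a single data frame (analysed as m = 1
#'   with complete-data inference).
#' @param comparison `c(intervention_arm, comparator_arm)`.
#' @param cost_col,effect_col Analysis column names.
#' @return List with `delta_cost` and `delta_effect` (`pooled_estimate`s for
#'   m >= 2, complete-data equivalents for a single table), `comparison`, `n`.
#' @export
incremental <- function(imps, comparison, cost_col = "cost_total",
                        effect_col = "qaly") {
  tabs <- if (inherits(imps, "imputation_set")) imps$imputations else list(imps)
  fits <- lapply(tabs, function(tab) {
    s <- .comparison_subset(tab, comparison)
    list(cost = .diff_in_means(s$tab[[cost_col]], s$is_ig),
         effect = .diff_in_means(s$tab[[effect_col]], s$is_ig))
  })
  dfcom <- fits[[1]]$cost$df
  pool_or_single <- function(part) {
    est <- vapply(fits, function(f) f[[part]]$coef, numeric(1))
    v <- vapply(fits, function(f) f[[part]]$var, numeric(1))
    if (length(est) >= 2) return(pool_rubin(est, v, dfcom = dfcom))
    se <- sqrt(v)
    stat <- est / se
    out <- list(point = est, W = v, B = 0, total_var = v, se = se, df = dfcom,
                statistic = stat, p_two = 2 * stats::pt(-abs(stat), dfcom),
                p_exceed = stats::pt(stat, dfcom), m = 1, degenerate = FALSE)
    class(out) <- "pooled_estimate"
    out
  }
  list(delta_cost = pool_or_single("cost"),
       delta_effect = pool_or_single("effect"),
       comparison = comparison,
       n = nrow(tabs[[1]][tabs[[1]]$arm %in% comparison, , drop = FALSE]))
}

#' ICER with dominance classification
#'
#' Places an incremental cost/effect pair on the cost-effectiveness plane.
#' The intervention is dominant iff it is cheaper and more effective
#' (dC < 0 and dE > 0) and dominated iff costlier and less effective
#' (dC > 0 and dE < 0); only otherwise is the ratio dC/dE meaningful.
#' South-west ratios (cheaper, less effective) carry an explicit note since
#' their interpretation differs from the north-east quadrant. A zero effect
#' difference yields no ratio (`undefined-ratio`), retaining the cost sign.
#'
#' @param delta_cost,delta_effect Incremental cost (euro) and effect, or
#'   `pooled_estimate`s (their points are used, p-values attached).
#' @return Object of class `icer_result`: `delta_cost`, `delta_effect`,
#'   `quadrant` (NE/NW/SE/SW or a boundary code), `label` (`dominant`,
#'   `dominated`, `ratio`, `undefined-ratio`), `icer`, `note`, `p_cost`,
#'   `p_effect`.
#' @export
icer <- function(delta_cost, delta_effect) {
  p_cost <- p_effect <- NA_real_
  if (inherits(delta_cost, "pooled_estimate")) {
    p_cost <- delta_cost$p_two; delta_cost <- delta_cost$point
  }
  if (inherits(delta_effect, "pooled_estimate")) {
    p_effect <- delta_effect$p_two; delta_effect <- delta_effect$point
  }
  dc <- delta_cost; de <- delta_effect
  quadrant <- if (de > 0 && dc > 0) "NE"
    else if (de < 0 && dc > 0) "NW"
    else if (de > 0 && dc < 0) "SE"
    else if (de < 0 && dc < 0) "SW"
    else if (de == 0) "dE=0 axis" else "dC=0 axis"
  if (dc < 0 && de > 0) {
    label <- "dominant"; val <- NA_real_; note <- "cheaper and more effective"
  } else if (dc > 0 && de < 0) {
    label <- "dominated"; val <- NA_real_; note <- "costlier and less effective"
  } else if (de == 0) {
    label <- "undefined-ratio"; val <- NA_real_
    note <- sprintf("zero effect difference; cost difference %s",
                    if (dc > 0) "positive" else if (dc < 0) "negative" else "zero")
  } else {
    label <- "ratio"; val <- dc / de
    note <- switch(quadrant,
      SW = "lower cost, lower effect: ratio below WTP favours the comparator trade-off",
      NE = "higher cost, higher effect",
      "on a cost axis")
  }
  out <- list(delta_cost = dc, delta_effect = de, quadrant = quadrant,
              label = label, icer = val, note = note,
              p_cost = p_cost, p_effect = p_effect)
  class(out) <- "icer_result"
  out
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("dC = %.2f, dE = %.6g  [%s]\n", x$delta_cost, x$delta_effect,
              x$quadrant))
  if (x$label == "ratio")
    cat(sprintf("ICER = %.0f per effect unit (%s)\n", x$icer, x$note))
  else cat(sprintf("%s (%s)\n", x$label, x$note))
  invisible(x)
}

#' Monetary net benefit
#'
#' `NB = wtp * effect - cost` per participant: the monetary value of the
#' effect at willingness-to-pay `wtp` minus the cost.
#'
#' @param cost Cost (euro).
#' @param effect Effect (QALY, VAS-QALY or DFD).
#' @param wtp Willingness-to-pay (euro per effect unit), >= 0.
#' @return Net benefit (euro).
#' @export
net_benefit <- function(cost, effect, wtp) {
  if (any(wtp < 0)) stop("willingness-to-pay must be >= 0", call. = FALSE)
  wtp * effect - cost
}

#' Net-benefit regression on a treatment dummy
#'
#' OLS of participant-level net benefit on the arm indicator; the slope is
#' exactly the difference in arm mean net benefit. Returns the one-sided
#' exceedance probability P(incremental NB > 0) from the t reference, the
#' quantity a CEAC plots.
#'
#' @param nb Net-benefit values.
#' @param is_ig Logical: intervention-arm membership.
#' @return List: `coef`, `se`, `var`, `df`, `statistic`, `p_exceed`, `p_two`.
#' @export
nbr_fit <- function(nb, is_ig) {
  if (length(unique(is_ig)) < 2)
    stop("net-benefit regression needs both arms", call. = FALSE)
  f <- .diff_in_means(nb, as.logical(is_ig))
  se <- sqrt(f$var)
  stat <- f$coef / se
  list(coef = f$coef, se = se, var = f$var, df = f$df, statistic = stat,
       p_exceed = stats::pt(stat, f$df), p_two = 2 * stats::pt(-abs(stat), f$df))
}

#' Cost-effectiveness acceptability curve from pooled net-benefit regressions
#'
#' For each willingness-to-pay value, a net-benefit regression is fitted per
#' completed dataset, the coefficient is pooled over imputations with
#' Rubin's rules, and the curve value is the pooled one-sided exceedance
#' probability that the incremental net benefit is positive.
#'
#' @inheritParams incremental
#' @param wtp_grid Strictly increasing willingness-to-pay grid (euro per
#'   effect unit).
#' @return Object of class `ceac_curve`: data frame (`wtp`, `prob`) with the
#'   comparison, effect column and grid in attributes.
#' @export
ceac <- function(imps, comparison, wtp_grid = .base_wtp_grid,
                 cost_col = "cost_total", effect_col = "qaly") {
  if (length(wtp_grid) == 0) stop("empty WTP grid", call. = FALSE)
  if (any(diff(wtp_grid) <= 0))
    stop("WTP grid must be strictly increasing", call. = FALSE)
  tabs <- if (inherits(imps, "imputation_set")) imps$imputations else list(imps)
  subs <- lapply(tabs, .comparison_subset, comparison = comparison)
  dfcom <- length(subs[[1]]$is_ig) - 2
  prob <- vapply(wtp_grid, function(lambda) {
    fits <- lapply(subs, function(s) {
      nb <- net_benefit(s$tab[[cost_col]], s$tab[[effect_col]], lambda)
      nbr_fit(nb, s$is_ig)
    })
    if (length(fits) >= 2) {
      pooled <- pool_rubin(vapply(fits, `[[`, numeric(1), "coef"),
                           vapply(fits, `[[`, numeric(1), "var"),
                           dfcom = dfcom)
      pooled$p_exceed
    } else fits[[1]]$p_exceed
  }, numeric(1))
  out <- data.frame(wtp = wtp_grid, prob = prob)
  class(out) <- c("ceac_curve", "data.frame")
  attr(out, "comparison") <- comparison
  attr(out, "effect_col") <- effect_col
  attr(out, "cost_col") <- cost_col
  out
}

#' Nonparametric bootstrap CEAC (cross-validation of the regression CEAC)
#'
#' Resamples participants with replacement within each arm of a single
#' completed dataset; the curve value at each willingness-to-pay is the
#' fraction of resamples with positive incremental net benefit.
#'
#' @param tab One completed (missingness-free) analysis table.
#' @param comparison,wtp_grid,cost_col,effect_col As in [ceac()].
#' @param n_boot Number of bootstrap resamples.
#' @param seed Seed for the resampling stream.
#' @return A `ceac_curve`.
#' @export
ceac_bootstrap <- function(tab, comparison, wtp_grid = .base_wtp_grid,
                           cost_col = "cost_total", effect_col = "qaly",
                           n_boot = 2000L, seed = 1L) {
  s <- .comparison_subset(tab, comparison)
  set.seed(seed)
  c1 <- s$tab[[cost_col]][s$is_ig]; e1 <- s$tab[[effect_col]][s$is_ig]
  c0 <- s$tab[[cost_col]][!s$is_ig]; e0 <- s$tab[[effect_col]][!s$is_ig]
  n1 <- length(c1); n0 <- length(c0)
  i1 <- matrix(sample.int(n1, n_boot * n1, replace = TRUE), nrow = n_boot)
  i0 <- matrix(sample.int(n0, n_boot * n0, replace = TRUE), nrow = n_boot)
  dc <- rowMeans(matrix(c1[i1], nrow = n_boot)) -
        rowMeans(matrix(c0[i0], nrow = n_boot))
  de <- rowMeans(matrix(e1[i1], nrow = n_boot)) -
        rowMeans(matrix(e0[i0], nrow = n_boot))
  prob <- vapply(wtp_grid, function(lambda) mean(lambda * de - dc > 0),
                 numeric(1))
  out <- data.frame(wtp = wtp_grid, prob = prob)
  class(out) <- c("ceac_curve", "data.frame")
  attr(out, "comparison") <- comparison
  attr(out, "effect_col") <- effect_col
  attr(out, "method") <- "bootstrap"
  out
}

#' @export
print.ceac_curve <- function(x, ...) {
  comp <- attr(x, "comparison")
  cat(sprintf("CEAC: %s vs %s (%s), %d WTP points in [%g, %g]\n",
              comp[1], comp[2], attr(x, "effect_col"), nrow(x),
              min(x$wtp), max(x$wtp)))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' @export
plot.ceac_curve <- function(x, add = FALSE, col = 1, lty = 1, ...) {
  if (!add) {
    graphics::plot(x$wtp, x$prob, type = "l", ylim = c(0, 1), col = col,
                   lty = lty, xlab = "Willingness-to-pay (euro per effect unit)",
                   ylab = "Probability cost-effective", ...)
  } else graphics::lines(x$wtp, x$prob, col = col, lty = lty, ...)
  invisible(x)
}

#' Sensitivity-scenario specification
#'
#' Scenario ids fix consistent defaults: `base` (QALY, societal perspective,
#' WTP grid 0--160,000 euro/QALY in 10,000 steps), `S1` (VAS-QALY), `S2`
#' (extended sample), `S3` (payer perspective), `S4` (primary-analysis
#' sample), `S5` (depression-free days, grid 0--200 euro/DFD with a 15
#' euro/DFD anchor).
#'
#' @param id One of `"base"`, `"S1"` ... `"S5"`.
#' @param wtp_grid Optional grid override.
#' @return Object of class `scenario_spec`: `id`, `effect_col`,
#'   `perspective`, `selector`, `wtp_grid`, `wtp_anchor`.
#' @export
scenario_spec <- function(id = c("base", "S1", "S2", "S3", "S4", "S5"),
                          wtp_grid = NULL) {
  id <- match.arg(id)
  spec <- switch(id,
    base = list(effect_col = "qaly", perspective = "societal",
                selector = "base", grid = .base_wtp_grid, anchor = NA_real_),
    S1 = list(effect_col = "qaly_vas", perspective = "societal",
              selector = "base", grid = .base_wtp_grid, anchor = NA_real_),
    S2 = list(effect_col = "qaly", perspective = "societal",
              selector = "extended", grid = .base_wtp_grid, anchor = NA_real_),
    S3 = list(effect_col = "qaly", perspective = "payer",
              selector = "base", grid = .base_wtp_grid, anchor = NA_real_),
    S4 = list(effect_col = "qaly", perspective = "societal",
              selector = "primary", grid = .base_wtp_grid, anchor = NA_real_),
    S5 = list(effect_col = "dfd", perspective = "societal",
              selector = "base", grid = .dfd_wtp_grid, anchor = .dfd_wtp_anchor)
  )
  out <- list(id = id, effect_col = spec$effect_col,
              perspective = spec$perspective, selector = spec$selector,
              wtp_grid = if (is.null(wtp_grid)) spec$grid else wtp_grid,
              wtp_anchor = spec$anchor)
  class(out) <- "scenario_spec"
  out
}

.select_rows <- function(tab, selector) {
  col <- switch(selector, base = "in_base", extended = "in_extended",
                primary = "in_primary", stop("unknown sample selector: ",
                                             selector, call. = FALSE))
  if (!col %in% names(tab)) return(tab)
  tab[tab[[col]], , drop = FALSE]
}

#' Run one scenario: pairwise ICERs and CEACs for all three comparisons
#'
#' Dispatches the scenario's effect column (QALY / VAS-QALY / DFD), cost
#' perspective (societal / payer), sample selector (base / extended /
#' primary) and WTP grid, and returns incremental estimates, ICER
#' classification and CEAC per pairwise comparison.
#'
#' @param imps An `imputation_set` of analysis tables ([prepare_analysis()]).
#' @param spec A [scenario_spec()] or a scenario id string.
#' @param comparisons List of comparisons (default: the three pairwise ones).
#' @return Object of class `cea_scenario`: list with `spec` and per-comparison
#'   `results` (`incremental`, `icer`, `ceac`).
#' @export
run_scenario <- function(imps, spec = "base",
                         comparisons = default_comparisons()) {
  if (is.character(spec)) spec <- scenario_spec(spec)
  if (!inherits(spec, "scenario_spec"))
    stop("spec must be a scenario id or scenario_spec", call. = FALSE)
  cost_col <- if (spec$perspective == "payer") "cost_total_payer" else "cost_total"
  sel <- function(obj) {
    if (inherits(obj, "imputation_set")) {
      obj$imputations <- lapply(obj$imputations, .select_rows,
                                selector = spec$selector)
      obj
    } else .select_rows(obj, spec$selector)
  }
  imps_s <- sel(imps)
  results <- lapply(comparisons, function(cmp) {
    inc <- incremental(imps_s, cmp, cost_col = cost_col,
                       effect_col = spec$effect_col)
    list(
      incremental = inc,
      icer = icer(inc$delta_cost, inc$delta_effect),
      ceac = ceac(imps_s, cmp, wtp_grid = spec$wtp_grid,
                  cost_col = cost_col, effect_col = spec$effect_col)
    )
  })
  out <- list(spec = spec, results = results)
  class(out) <- "cea_scenario"
  out
}

#' @export
print.cea_scenario <- function(x, ...) {
  cat("Scenario", x$spec$id, "-", x$spec$effect_col, "effect,",
      x$spec$perspective, "perspective,", x$spec$selector, "sample\n")
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    ic <- r$icer
    cat(sprintf("  %-28s dC %8.0f (p=%.2f)  dE %9.4g (p=%.2f)  %s\n",
                nm, ic$delta_cost, ic$p_cost, ic$delta_effect, ic$p_effect,
                if (ic$label == "ratio") sprintf("ICER %.0f", ic$icer)
                else ic$label))
  }
  invisible(x)
}

#' Subgroup CEACs
#'
#' Restricts the analysis to each level of a grouping variable and computes
#' the scenario CEAC per level. Age is grouped into terciles computed on the
#' pooled baseline sample. Levels with an empty arm are skipped with a
#' warning.
#'
#' @param imps Analysis `imputation_set`.
#' @param grouping Variable name: one of the table's columns, or `"age"` for
#'   terciles.
#' @param spec Scenario (default base case).
#' @param comparisons Comparisons to run (default all three).
#' @return Named list (one element per level) of per-comparison CEACs.
#' @export
subgroup_ceac <- function(imps, grouping, spec = "base",
                          comparisons = default_comparisons()) {
  if (is.character(spec)) spec <- scenario_spec(spec)
  tab1 <- imps$imputations[[1]]
  if (!grouping %in% names(tab1))
    stop("unknown grouping variable: ", grouping, call. = FALSE)
  g <- tab1[[grouping]]
  if (identical(grouping, "age")) {
    g <- .age_terciles(g)
  } else if (!is.factor(g)) g <- factor(g)
  cost_col <- if (spec$perspective == "payer") "cost_total_payer" else "cost_total"
  out <- list()
  for (lev in levels(g)) {
    keep <- which(g == lev)
    sub <- imps
    sub$imputations <- lapply(imps$imputations,
                              function(t) t[keep, , drop = FALSE])
    arms_ok <- vapply(comparisons, function(cmp)
      all(table(factor(sub$imputations[[1]]$arm))[cmp] >= 2), logical(1))
    if (!all(arms_ok)) {
      warning("subgroup level '", lev, "' has an empty arm; skipped")
      next
    }
    out[[lev]] <- lapply(comparisons, function(cmp)
      ceac(sub, cmp, wtp_grid = spec$wtp_grid, cost_col = cost_col,
           effect_col = spec$effect_col))
  }
  out
}

# rank-based terciles on the pooled baseline sample: equal group sizes
# (+/- 1) even when rounded ages tie at a boundary
.age_terciles <- function(age) {
  r <- rank(age, ties.method = "first")
  cut(r, breaks = stats::quantile(r, c(0, 1/3, 2/3, 1)),
      include.lowest = TRUE, labels = c("age_T1", "age_T2", "age_T3"))
}

#' Pairwise baseline balance tests across the three arms
#'
#' For every variable and every arm pair: Welch's unequal-variance t test
#' for continuous variables, a chi-square test for categorical ones.
#' Constant variables are skipped with a flag.
#'
#' @param table Trial table (one dataset, typically pre-imputation with
#'   complete baseline covariates).
#' @param vars Variables to test (defaults to baseline covariates present).
#' @return Data frame: `variable`, `arm1`, `arm2`, `test`, `statistic`, `p`.
#' @export
baseline_balance <- function(table,
                             vars = intersect(c("age", "gender", "city_size",
                                                "insurance", "phq_t0",
                                                "eq5d_t0", "vas_t0",
                                                "cost_pre"), names(table))) {
  arms <- levels(factor(table$arm))
  if (length(arms) < 2) stop("need >= 2 arms", call. = FALSE)
  pairs <- utils::combn(arms, 2, simplify = FALSE)
  rows <- list()
  for (v in vars) {
    x <- table[[v]]
    for (pr in pairs) {
      xi <- x[table$arm == pr[1]]; xj <- x[table$arm == pr[2]]
      if (length(unique(stats::na.omit(c(xi, xj)))) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, arm1 = pr[1], arm2 = pr[2], test = "skipped-constant",
          statistic = NA_real_, p = NA_real_)
        next
      }
      if (is.numeric(x)) {
        tt <- stats::t.test(xi, xj, var.equal = FALSE)
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, arm1 = pr[1], arm2 = pr[2], test = "welch-t",
          statistic = unname(tt$statistic), p = tt$p.value)
      } else {
        ct <- suppressWarnings(stats::chisq.test(table(
          factor(c(xi, xj)),
          rep(pr, c(length(xi), length(xj))))))
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, arm1 = pr[1], arm2 = pr[2], test = "chi-square",
          statistic = unname(ct$statistic), p = ct$p.value)
      }
    }
  }
  do.call(rbind, rows)
}
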