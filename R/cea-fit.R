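# Front end: cea() fits the full evaluation (imputation -> outcomes ->
# costing -> pooled pairwise incremental analysis, CEACs, scenarios) and
# returns a classed object with the usual modelling-idiom methods.

#' Attach analysis columns to every completed dataset
#'
#' Computes per-participant outcomes ([compute_outcomes()]) and cost
#' aggregates ([compute_costs()]) for each completed table of an imputation
#' set (or for a single complete table), adding the columns the evaluation
#' core consumes: `qaly`, `qaly_vas`, `dfd`, `cost_total`,
#' `cost_total_payer`, `cost_pre`.
#'
#' @param imps An `imputation_set` or a single complete trial table.
#' @param unit_costs Unit-cost table.
#' @param daily_wage Gross daily wage (euro) for the human capital approach.
#' @param dfd_rule,dfd_threshold Depression-free-day rule (see
#'   [depression_free_days()]).
#' @param horizon Follow-up horizon in days.
#' @return Same shape as the input, with analysis columns added.
#' @export
prepare_analysis <- function(imps, unit_costs = default_unit_costs(),
                             daily_wage = 150, dfd_rule = "binary",
                             dfd_threshold = 5, horizon = 180) {
  enrich <- function(tab) {
    out <- compute_outcomes(tab, dfd_rule = dfd_rule,
                            dfd_threshold = dfd_threshold, horizon = horizon)
    costs <- compute_costs(tab, unit_costs = unit_costs,
                           daily_wage = daily_wage)
    cbind(tab, out,
          costs[, c("cost_total", "cost_total_payer", "cost_pre")])
  }
  if (inherits(imps, "imputation_set")) {
    imps$imputations <- lapply(imps$imputations, enrich)
    imps
  } else enrich(imps)
}

#' Fit a trial-based cost-effectiveness analysis
#'
#' The one-stop estimator: takes a participant-level trial table (with or
#' without missing cells), multiply imputes it by chained equations,
#' constructs QALYs, VAS-QALYs, depression-free days and perspective-specific
#' cost totals per completed dataset, and estimates the pooled pairwise
#' incremental costs and effects, ICER dominance classification and
#' net-benefit-regression CEACs for the requested scenarios, plus baseline
#' balance tests.
#'
#' @param data Trial table, e.g. from [generate_trial()] (+
#'   [apply_missingness()]) or [read_trial_table()].
#' @param scenarios Character vector of scenario ids (see [scenario_spec()]).
#' @param m,iterations Multiple-imputation settings; tables without missing
#'   cells use a single analysis dataset.
#' @param unit_costs,daily_wage Costing inputs.
#' @param dfd_rule,dfd_threshold Depression-free-day rule.
#' @param subgroups Optional character vector of grouping variables for
#'   explorative subgroup CEACs (base-case scenario).
#' @param wtp_grid Optional WTP grid override applied to every scenario.
#' @param seed Master seed for the imputation streams.
#' @return Object of class `cea`: list with `scenarios` (per-id
#'   `cea_scenario`), `balance`, `subgroups`, `imputations`, `m`, `seed`,
#'   `call`.
#' @export
cea <- function(data, scenarios = "base", m = 10L, iterations = 10L,
                unit_costs = default_unit_costs(), daily_wage = 150,
                dfd_rule = "binary", dfd_threshold = 5, subgroups = NULL,
                wtp_grid = NULL, seed = 1L) {
  stopifnot(is.data.frame(data))
  has_na <- anyNA(data)
  imps <- if (has_na) impute_chained(data, m = m, iterations = iterations,
                                     seed = seed)
          else impute_chained(data, m = 1L, iterations = 1L, seed = seed)
  imps <- prepare_analysis(imps, unit_costs = unit_costs,
                           daily_wage = daily_wage, dfd_rule = dfd_rule,
                           dfd_threshold = dfd_threshold)
  scen <- lapply(scenarios, function(id)
    run_scenario(imps, scenario_spec(id, wtp_grid = wtp_grid)))
  names(scen) <- scenarios
  sub <- NULL
  if (!is.null(subgroups)) {
    sub <- lapply(subgroups, function(g) subgroup_ceac(imps, g))
    names(sub) <- subgroups
  }
  out <- list(
    scenarios = scen,
    balance = baseline_balance(prepare_analysis(
      if (has_na) imps$imputations[[1]] else data,
      unit_costs = unit_costs, daily_wage = daily_wage)),
    subgroups = sub,
    imputations = imps,
    m = imps$m, seed = seed, call = match.call()
  )
  class(out) <- "cea"
  out
}

#' @export
print.cea <- function(x, ...) {
  cat("Trial-based cost-effectiveness analysis\n")
  cat(sprintf("  %d completed dataset(s), seed %d\n", x$m, x$seed))
  for (s in x$scenarios) print(s)
  invisible(x)
}

#' @export
summary.cea <- function(object, scenario = names(object$scenarios)[1], ...) {
  sc <- object$scenarios[[scenario]]
  rows <- lapply(names(sc$results), function(nm) {
    r <- sc$results[[nm]]; ic <- r$icer
    data.frame(
      comparison = nm,
      delta_cost = ic$delta_cost, p_cost = ic$p_cost,
      delta_effect = ic$delta_effect, p_effect = ic$p_effect,
      quadrant = ic$quadrant, label = ic$label, icer = ic$icer,
      prob_at_wtp0 = r$ceac$prob[1],
      prob_at_wtp_max = r$ceac$prob[nrow(r$ceac)]
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "scenario") <- scenario
  class(out) <- c("summary.cea", "data.frame")
  out
}

#' @export
print.summary.cea <- function(x, ...) {
  cat("Scenario:", attr(x, "scenario"), "\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.cea <- function(object, scenario = names(object$scenarios)[1], ...) {
  sc <- object$scenarios[[scenario]]
  unlist(lapply(stats::setNames(names(sc$results), names(sc$results)),
                function(nm) {
    r <- sc$results[[nm]]
    c(delta_cost = r$incremental$delta_cost$point,
      delta_effect = r$incremental$delta_effect$point)
  }))
}

#' @export
plot.cea <- function(x, scenario = names(x$scenarios)[1], ...) {
  sc <- x$scenarios[[scenario]]
  cols <- seq_along(sc$results)
  first <- TRUE
  for (i in cols) {
    plot(sc$results[[i]]$ceac, add = !first, col = i,
         main = if (first) paste("CEAC -", scenario) else NULL, ...)
    first <- FALSE
  }
  graphics::legend("topright", legend = names(sc$results), col = cols,
                   lty = 1, cex = 0.8, bty = "n")
  if (!is.na(sc$spec$wtp_anchor))
    graphics::abline(v = sc$spec$wtp_anchor, lty = 3)
  invisible(x)
}
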