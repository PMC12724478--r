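# Costing: resource-use quantities -> per-participant category costs ->
# direct/indirect/total aggregates under a societal or payer perspective.

#' Default unit-cost table
#'
#' A synthetic unit-cost table in the style of national standard unit-cost
#' catalogues (one price per resource category, price year 2022). It is a
#' placeholder for a user-supplied catalogue, not a published one.
#'
#' @return Data frame with columns `category`, `unit_cost` (euro per unit),
#'   `unit`, `price_year`.
#' @export
default_unit_costs <- function() {
  data.frame(
    category = .direct_categories,
    unit_cost = c(575, 45, 100, 35, 40, 22, 27.5),
    unit = c("day", "contact", "session", "contact", "hour", "hour", "pack"),
    price_year = 2022L,
    stringsAsFactors = FALSE
  )
}

validate_unit_costs <- function(table) {
  req <- c("category", "unit_cost")
  if (!all(req %in% names(table)))
    stop("unit-cost table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(table$category))
    stop("duplicate category keys in unit-cost table", call. = FALSE)
  if (any(table$unit_cost < 0))
    stop("unit costs must be >= 0", call. = FALSE)
  if ("price_year" %in% names(table) &&
      any(table$price_year < 1000 | table$price_year > 9999))
    stop("price_year must be a 4-digit year", call. = FALSE)
  invisible(table)
}

#' Read a unit-cost table from delimited text
#'
#' @param path Delimited text file with a header row (tab or comma
#'   separated); must contain `category` and `unit_cost` columns.
#' @return Validated unit-cost data frame.
#' @export
read_unit_costs <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  validate_unit_costs(utils::read.table(path, sep = sep, header = TRUE,
                                        stringsAsFactors = FALSE))
}

#' Price resource-use quantities with a unit-cost table
#'
#' `cost = quantity * unit_cost` per category; medication is costed per pack
#' through its own key like any other category.
#'
#' @param quantities Named numeric vector (category -> quantity) or a data
#'   frame whose columns are categories.
#' @param unit_costs Unit-cost table as from [default_unit_costs()].
#' @return Costs in the same shape as `quantities`.
#' @export
apply_unit_costs <- function(quantities, unit_costs = default_unit_costs()) {
  validate_unit_costs(unit_costs)
  price <- stats::setNames(unit_costs$unit_cost, unit_costs$category)
  cats <- if (is.data.frame(quantities)) names(quantities) else names(quantities)
  unknown <- setdiff(cats, names(price))
  if (length(unknown))
    stop("unknown cost category: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  qv <- if (is.data.frame(quantities)) as.matrix(quantities) else quantities
  if (any(qv < 0, na.rm = TRUE))
    stop("quantities must be >= 0", call. = FALSE)
  if (is.data.frame(quantities)) {
    out <- quantities
    for (v in cats) out[[v]] <- quantities[[v]] * price[[v]]
    out
  } else {
    quantities * price[cats]
  }
}

#' Productivity loss under the human capital approach
#'
#' Values absence time at the gross wage: `absence_days * daily_wage`.
#'
#' @param absence_days Nonnegative days absent.
#' @param daily_wage Nonnegative gross wage (euro per day).
#' @return Indirect cost (euro).
#' @export
productivity_loss_hca <- function(absence_days, daily_wage) {
  if (any(absence_days < 0, na.rm = TRUE) || any(daily_wage < 0, na.rm = TRUE))
    stop("absence_days and daily_wage must be >= 0", call. = FALSE)
  absence_days * daily_wage
}

#' Adjust a cost to a target price year via consumer price indices
#'
#' @param cost Cost at the source price year (euro).
#' @param cpi_source,cpi_target Positive consumer-price-index values for the
#'   source and target years.
#' @return `cost * cpi_target / cpi_source`.
#' @export
adjust_prices <- function(cost, cpi_source, cpi_target) {
  if (any(cpi_source <= 0) || any(cpi_target <= 0))
    stop("CPI values must be > 0", call. = FALSE)
  cost * cpi_target / cpi_source
}

#' Aggregate a cost ledger to direct / indirect / total
#'
#' Societal perspective: direct = sum of the seven direct categories,
#' total = direct + indirect. Payer perspective: informal care is excluded
#' from direct costs and indirect costs are excluded entirely (configurable
#' via `payer_includes_indirect`).
#'
#' @param ledger Data frame with one column per direct category (euro) and an
#'   `indirect` column.
#' @param perspective `"societal"` or `"payer"`.
#' @param payer_includes_indirect Include indirect costs under the payer
#'   perspective (default `FALSE`).
#' @return Data frame with columns `direct`, `indirect`, `total`.
#' @export
aggregate_costs <- function(ledger, perspective = c("societal", "payer"),
                            payer_includes_indirect = FALSE) {
  perspective <- match.arg(perspective)
  cats <- intersect(.direct_categories, names(ledger))
  indirect <- if ("indirect" %in% names(ledger)) ledger$indirect else 0
  if (perspective == "payer") {
    cats <- setdiff(cats, "informal_care")
    if (!payer_includes_indirect) indirect <- 0 * indirect
  }
  direct <- rowSums(as.data.frame(ledger[, cats, drop = FALSE]))
  data.frame(direct = direct, indirect = indirect, total = direct + indirect)
}

#' Assign the randomisation-window direct costs to the post period
#'
#' Direct costs accruing between randomisation (T0) and the post-baseline
#' survey (T1) belong to the treatment (post) period, because the
#' intervention happens immediately after randomisation; indirect costs
#' assessed at T0 remain pre-period.
#'
#' @param window_direct Nonnegative direct costs accrued in the T0--T1 window
#'   (euro, scalar or per-participant vector).
#' @param pre,post Pre- and post-period total direct costs.
#' @return List with updated `pre` and `post`.
#' @export
split_pre_post <- function(window_direct, pre, post) {
  if (any(window_direct < 0, na.rm = TRUE))
    stop("window costs must be >= 0", call. = FALSE)
  list(pre = pre, post = post + window_direct)
}

#' Build per-participant cost aggregates from a trial table
#'
#' Converts the pre/post resource-use quantity columns to category costs via
#' the unit-cost table, values absence days via the human capital approach,
#' and returns follow-up (post-period) totals under both perspectives plus
#' the pre-period societal total for baseline balance checks.
#'
#' @param table Trial table with `q_pre_*`, `q_post_*`, `absence_pre`,
#'   `absence_post` columns.
#' @param unit_costs Unit-cost table.
#' @param daily_wage Gross daily wage (euro).
#' @param payer_includes_indirect See [aggregate_costs()].
#' @return Data frame: per-category post costs, `direct`, `indirect`,
#'   `cost_total` (societal), `cost_total_payer`, `cost_pre`.
#' @export
compute_costs <- function(table, unit_costs = default_unit_costs(),
                          daily_wage = 150, payer_includes_indirect = FALSE) {
  validate_unit_costs(unit_costs)
  post_q <- table[, paste0("q_post_", .direct_categories)]
  names(post_q) <- .direct_categories
  post <- apply_unit_costs(post_q, unit_costs)
  post$indirect <- productivity_loss_hca(table$absence_post, daily_wage)
  soc <- aggregate_costs(post, "societal")
  pay <- aggregate_costs(post, "payer",
                         payer_includes_indirect = payer_includes_indirect)
  pre_q <- table[, paste0("q_pre_", .direct_categories)]
  names(pre_q) <- .direct_categories
  pre <- apply_unit_costs(pre_q, unit_costs)
  pre$indirect <- productivity_loss_hca(table$absence_pre, daily_wage)
  cbind(post,
        data.frame(direct = soc$direct,
                   cost_total = soc$total,
                   cost_total_payer = pay$total,
                   cost_pre = aggregate_costs(pre, "societal")$total))
}
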