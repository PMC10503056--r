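# Incremental cost-effectiveness analysis.
#
# Per-person lifetime outcomes are scaled to program level (weighted mean per
# screened person times the program's annual screening capacity), compared
# against the base case, and the non-dominated set identified: strong
# dominance (more QALYs at lower cost) first, then iterative removal of
# extended (weakly) dominated scenarios until pairwise ICERs increase
# strictly along the cost-ordered frontier.

#' Scale per-person outcomes to program level
#'
#' Program total = survey-weighted mean per screened person x screening
#' capacity, separately for costs and QALYs. Invariant to rescaling all
#' weights by a constant.
#'
#' @param outcomes Per-person outcomes from [simulate_cohort()].
#' @param weights Survey weights for the same rows (non-negative, positive
#'   total).
#' @param capacity Persons screened per program year.
#' @return List with `total_cost`, `total_qalys`, `per_person_cost`,
#'   `per_person_qalys`, `capacity`.
#' @export
scale_to_program <- function(outcomes, weights, capacity) {
  if (length(weights) == 0L || sum(weights) <= 0) {
    stop_input("total survey weight must be positive")
  }
  if (any(weights < 0)) stop_input("weights must be non-negative")
  pc <- sum(weights * outcomes$disc_costs) / sum(weights)
  pq <- sum(weights * outcomes$disc_qalys) / sum(weights)
  list(total_cost = pc * capacity, total_qalys = pq * capacity,
       per_person_cost = pc, per_person_qalys = pq, capacity = capacity)
}

#' Increment of one scenario over a comparator
#'
#' @param base,alt Lists with `total_cost` and `total_qalys` (e.g. from
#'   [scale_to_program()]).
#' @return List with `d_cost`, `d_qaly`, `icer`, `label`. Labels: `"base"`
#'   is never produced here; `"equivalent"` when both increments are 0;
#'   `"undefined"` when only the QALY increment is 0; `"cost_saving"` when
#'   the alternative is cheaper (for a cheaper-and-less-effective scenario
#'   the ratio is still reported: savings per QALY forgone); `"icer"`
#'   otherwise, with `icer = d_cost / d_qaly`.
#' @export
incremental <- function(base, alt) {
  d_cost <- alt$total_cost - base$total_cost
  d_qaly <- alt$total_qalys - base$total_qalys
  if (d_qaly == 0) {
    label <- if (d_cost == 0) "equivalent" else "undefined"
    return(list(d_cost = d_cost, d_qaly = d_qaly, icer = NA_real_,
                label = label))
  }
  icer <- d_cost / d_qaly
  label <- if (d_cost < 0) "cost_saving" else "icer"
  list(d_cost = d_cost, d_qaly = d_qaly, icer = icer, label = label)
}

#' Dominance analysis and cost-effectiveness frontier
#'
#' Strong dominance: another scenario has at least as many QALYs at no
#' higher cost, with at least one strict inequality (exact ties keep the
#' lexicographically smaller `scenario_id`). Extended (weak) dominance:
#' scenarios are removed iteratively until the pairwise ICERs along the
#' cost-ordered survivors are strictly increasing. The frontier is the
#' surviving set.
#'
#' @param results `data.frame` with columns `scenario_id`, `cost`, `qalys`.
#' @return `results` with added columns `dominance` (`"frontier"`,
#'   `"dominated_strong"`, `"dominated_weak"`) and `on_frontier`, plus
#'   attribute `"frontier"`: the frontier rows ordered by increasing cost
#'   with their pairwise `icer_vs_previous`.
#' @export
dominance_and_frontier <- function(results) {
  stopifnot(all(c("scenario_id", "cost", "qalys") %in% names(results)))
  n <- nrow(results)
  label <- rep("frontier", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ci <- results$cost[i]; qi <- results$qalys[i]
      cj <- results$cost[j]; qj <- results$qalys[j]
      if (cj <= ci && qj >= qi && (cj < ci || qj > qi)) {
        label[i] <- "dominated_strong"
        break
      }
      if (cj == ci && qj == qi &&
          results$scenario_id[j] < results$scenario_id[i]) {
        label[i] <- "dominated_strong" # exact tie: keep smaller id
        break
      }
    }
  }
  surv <- which(label == "frontier")
  surv <- surv[order(results$cost[surv], results$scenario_id[surv])]
  repeat {
    k <- length(surv)
    if (k < 3L) break
    icers <- diff(results$cost[surv]) / diff(results$qalys[surv])
    viol <- which(utils::head(icers, -1) >= utils::tail(icers, -1))
    if (!length(viol)) break
    drop_i <- surv[viol[1] + 1L]
    label[drop_i] <- "dominated_weak"
    surv <- setdiff(surv, drop_i)
  }
  results$dominance <- label
  results$on_frontier <- label == "frontier"
  fr <- results[surv, , drop = FALSE]
  fr$icer_vs_previous <- c(NA_real_,
                           if (nrow(fr) > 1)
                             diff(fr$cost) / diff(fr$qalys) else numeric(0))
  attr(results, "frontier") <- fr
  results
}

#' Classify an ICER against GDP-multiple thresholds
#'
#' Returns the smallest multiplier `m` with `icer <= m * gdp_per_capita`
#' (boundary inclusive), or `"above_1x"`. Cost-saving results are classified
#' `"cost_saving"` before any threshold comparison.
#'
#' @param icer ICER in USD/QALY (may be `NA` for labelled results).
#' @param label Incremental label from [incremental()].
#' @param gdp_per_capita GDP per capita in USD (default 4083).
#' @param multipliers Increasing threshold multipliers.
#' @return Character category, e.g. `"le_0.25x"`.
#' @export
threshold_classify <- function(icer, label = "icer", gdp_per_capita = 4083,
                               multipliers = c(0.25, 0.5, 1.0)) {
  if (identical(label, "cost_saving")) return("cost_saving")
  if (is.na(icer)) return("undefined")
  for (m in sort(multipliers)) {
    if (icer <= m * gdp_per_capita) return(paste0("le_", format(m), "x"))
  }
  "above_1x"
}

#' Incremental results by age band
#'
#' Splits matched per-person scenario and comparator outcomes into half-open
#' age bands and mirrors [scale_to_program()] within each band, yielding
#' per-band incremental costs, QALYs and ICERs. Empty bands are omitted with
#' a notice.
#'
#' @param age Age at screening per person.
#' @param weight Survey weight per person.
#' @param cost_alt,qaly_alt,cost_base,qaly_base Matched per-person
#'   discounted outcomes under the scenario and the comparator.
#' @param band_width Band width in years (default 5).
#' @param capacity Program capacity used for the within-band scaling.
#' @return `data.frame` with one row per non-empty band: `age_lo`, `age_hi`,
#'   `n`, `d_cost`, `d_qaly`, `icer`.
#' @export
subgroup_by_age <- function(age, weight, cost_alt, qaly_alt, cost_base,
                            qaly_base, band_width = 5, capacity = hlc_capacity()) {
  lo0 <- floor(min(age) / band_width) * band_width
  band_lo <- lo0 + band_width * ((floor(age) - lo0) %/% band_width)
  out <- lapply(sort(unique(band_lo)), function(b) {
    idx <- which(band_lo == b)
    if (!length(idx) || sum(weight[idx]) <= 0) {
      notify("omitting empty age band [", b, ", ", b + band_width, ")")
      return(NULL)
    }
    w <- weight[idx]
    d_cost <- (sum(w * cost_alt[idx]) - sum(w * cost_base[idx])) / sum(w) * capacity
    d_qaly <- (sum(w * qaly_alt[idx]) - sum(w * qaly_base[idx])) / sum(w) * capacity
    data.frame(age_lo = b, age_hi = b + band_width, n = length(idx),
               d_cost = d_cost, d_qaly = d_qaly,
               icer = if (d_qaly != 0) d_cost / d_qaly else NA_real_)
  })
  do.call(rbind, out)
}

#' Assemble the scenario-level CEA table
#'
#' Joins program totals with increments versus the base case, dominance
#' labels, frontier membership, the ICER versus the nearest cheaper frontier
#' scenario, and the GDP-threshold category.
#'
#' @param program_totals Named list (by scenario id) of [scale_to_program()]
#'   results.
#' @param base_id Scenario id of the comparator.
#' @param gdp_per_capita GDP per capita for threshold classification.
#' @return `data.frame`, one row per scenario, with attribute `"frontier"`.
#' @export
cea_table <- function(program_totals, base_id, gdp_per_capita = 4083) {
  ids <- names(program_totals)
  if (!base_id %in% ids) stop_input("base scenario not found: ", base_id)
  base <- program_totals[[base_id]]
  rows <- lapply(ids, function(id) {
    tot <- program_totals[[id]]
    if (id == base_id) {
      data.frame(scenario_id = id, cost = tot$total_cost, qalys = tot$total_qalys,
                 d_cost = 0, d_qaly = 0, icer = NA_real_, label = "base",
                 stringsAsFactors = FALSE)
    } else {
      inc <- incremental(base, tot)
      data.frame(scenario_id = id, cost = tot$total_cost, qalys = tot$total_qalys,
                 d_cost = inc$d_cost, d_qaly = inc$d_qaly, icer = inc$icer,
                 label = inc$label, stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  tab <- dominance_and_frontier(tab)
  fr <- attr(tab, "frontier")
  tab$icer_vs_frontier <- fr$icer_vs_previous[match(tab$scenario_id,
                                                    fr$scenario_id)]
  tab$threshold_category <- mapply(threshold_classify, tab$icer, tab$label,
                                   MoreArgs = list(gdp_per_capita = gdp_per_capita))
  attr(tab, "frontier") <- fr
  tab
}
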