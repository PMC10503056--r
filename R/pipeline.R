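# Pipeline orchestration and reporting.
#
# `run_pipeline()` ties the stages together: population (generated or
# loaded), risk scoring, scenario screening, lifetime simulation, CEA table
# and frontier, optional sensitivity analyses, figures, and a JSON run
# manifest recording seeds and parameters so any output can be regenerated.

#' Prepare a scenario for repeated evaluation
#'
#' Screens the population once (eligibility, classification, treatment
#' plans); the result can then be re-simulated cheaply under many parameter
#' sets (DSA/PSA), since plans depend only on the scenario and its tool.
#'
#' @param population Validated population.
#' @param scenario A `scenario_spec`.
#' @param tools Risk-tool registry.
#' @return List with the screened indices, rows, plans, summary and
#'   scenario.
#' @export
prepare_scenario <- function(population, scenario, tools = default_risk_tools()) {
  sc <- screen_cohort(population, scenario, tools)
  list(scenario = scenario, idx = which(sc$eligible), screened = sc$screened,
       plan = sc$plan, summary = sc$summary, risk = sc$risk)
}

#' Simulate the no-program counterfactual for a screened cohort
#'
#' The same persons propagated through the Markov model with no screening
#' visit, no treatment and no follow-up; the reference against which a
#' program's costs and QALYs are measured.
#'
#' @inheritParams evaluate_prepared
#' @return Per-person outcomes from [simulate_cohort()].
#' @export
untreated_outcomes <- function(prep, risks, params) {
  idx <- prep$idx
  simulate_cohort(prep$screened, null_plan(length(idx)), params,
                  risks$p1_chd[idx], risks$p1_stroke[idx],
                  include_screening_cost = FALSE)
}

#' Evaluate a prepared scenario under one parameter set
#'
#' Simulates the screened cohort twice — under the scenario's treatment
#' plans and under the no-program counterfactual — and scales the net
#' (program-attributable) per-person costs and QALYs to program level.
#' Netting against the same cohort's counterfactual is what makes programs
#' with different eligible age groups comparable: the demographic
#' composition of the cohort cancels and only the program's own effect
#' remains.
#'
#' @param prep Output of [prepare_scenario()].
#' @param population The same population the scenario was prepared on.
#' @param risks Ground-truth probabilities from
#'   [event_risk_probabilities()] on the full population.
#' @param params A `parameter_set`.
#' @param untreated Optional precomputed [untreated_outcomes()] for this
#'   cohort and parameter set (they depend only on the age rule, so they can
#'   be shared across scenarios).
#' @return [scale_to_program()] result for the scenario's net outcomes.
#' @export
evaluate_prepared <- function(prep, population, risks, params,
                              untreated = NULL) {
  idx <- prep$idx
  treated <- simulate_cohort(prep$screened, prep$plan, params,
                             risks$p1_chd[idx], risks$p1_stroke[idx],
                             mode = prep$scenario$mode)
  if (is.null(untreated)) untreated <- untreated_outcomes(prep, risks, params)
  net <- data.frame(
    disc_costs = treated$disc_costs - untreated$disc_costs,
    disc_qalys = treated$disc_qalys - untreated$disc_qalys
  )
  scale_to_program(net, prep$screened$survey_weight, prep$scenario$capacity)
}

## Shared untreated runs, one per eligibility rule (the cohort is identical
## for every scenario with the same age rule).
untreated_cache_by_rule <- function(preps, risks, params) {
  cache <- list()
  for (prep in preps) {
    rule <- prep$scenario$age_rule
    if (is.null(cache[[rule]])) {
      cache[[rule]] <- untreated_outcomes(prep, risks, params)
    }
  }
  cache
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the population, screens it under every scenario,
#' simulates lifetime outcomes, and assembles the CEA table with dominance
#' labels and the frontier. Optionally runs the one-way, pill-disutility and
#' probabilistic sensitivity analyses, writes CSV outputs and figures under
#' `outdir`, and records a JSON run manifest.
#'
#' @param population A population `data.frame`, or `NULL` to generate one
#'   from `pop_spec`.
#' @param pop_spec A [population_spec()] used when `population` is `NULL`.
#' @param scenarios Named list of `scenario_spec`s; defaults to
#'   [build_scenario_grid()].
#' @param params A `parameter_set`.
#' @param tools Risk-tool registry.
#' @param event_tool Registry key of the ground-truth event tool.
#' @param dsa Run the one-way deterministic sensitivity analysis on the most
#'   effective frontier scenario.
#' @param psa_draws Number of PSA draws (0 disables the PSA).
#' @param pill_disutility Pill disutility analysed in the dedicated
#'   sensitivity run (0 disables it).
#' @param seed Root seed; expanded into per-stage streams.
#' @param outdir Output directory for CSVs, figures and the manifest
#'   (`NULL`: nothing written).
#' @return List of class `cvd_pipeline_result`: `population`, `scenarios`,
#'   `screening` (per-scenario commencement summaries), `cea` (table with
#'   frontier attribute), `frontier`, `dsa`, `pill`, `psa`, `manifest`.
#' @export
run_pipeline <- function(population = NULL,
                         pop_spec = population_spec(n = 5000, seed = 1),
                         scenarios = NULL,
                         params = default_parameters(),
                         tools = default_risk_tools(),
                         event_tool = "who2019_lab",
                         dsa = FALSE, psa_draws = 0, pill_disutility = 0,
                         seed = 1, outdir = NULL) {
  if (is.null(population)) {
    pop_spec$seed <- child_seed(seed, 1L)
    population <- generate_population(pop_spec)
  }
  validate_population(population)
  if (is.null(scenarios)) scenarios <- build_scenario_grid()
  if (is.null(names(scenarios))) {
    names(scenarios) <- vapply(scenarios, `[[`, character(1), "scenario_id")
  }
  base_ids <- names(scenarios)[vapply(scenarios, `[[`, logical(1), "base_case")]
  if (length(base_ids) != 1L) {
    stop_input("exactly one scenario must be flagged base_case; found ",
               length(base_ids))
  }
  risks <- event_risk_probabilities(population, tools, event_tool)
  preps <- lapply(scenarios, prepare_scenario, population = population,
                  tools = tools)
  untreated <- untreated_cache_by_rule(preps, risks, params)
  totals <- lapply(preps, function(prep) {
    evaluate_prepared(prep, population, risks, params,
                      untreated = untreated[[prep$scenario$age_rule]])
  })
  screening <- do.call(rbind, lapply(names(preps), function(id) {
    cbind(scenario_id = id, preps[[id]]$summary)
  }))
  cea <- cea_table(totals, base_ids, gdp_per_capita = params$gdp_per_capita)
  frontier <- attr(cea, "frontier")

  dsa_res <- NULL
  if (isTRUE(dsa)) {
    top_id <- frontier$scenario_id[nrow(frontier)]
    if (top_id == base_ids && nrow(frontier) > 1) {
      top_id <- frontier$scenario_id[nrow(frontier) - 1L]
    }
    dsa_res <- one_way(population, scenarios[[top_id]], scenarios[[base_ids]],
                       default_one_way_variations(), params, tools)
  }
  pill_res <- NULL
  if (pill_disutility > 0) {
    pill_res <- pill_disutility_analysis(
      population, scenarios[setdiff(names(scenarios), base_ids)],
      scenarios[[base_ids]], pill_disutility, params, tools)
  }
  psa_res <- NULL
  if (psa_draws > 0) {
    fr_ids <- setdiff(frontier$scenario_id, base_ids)
    psa_res <- run_psa(population, scenarios[fr_ids], scenarios[[base_ids]],
                       n_draws = psa_draws, seed = child_seed(seed, 2L),
                       icer_threshold = 0.5 * params$gdp_per_capita,
                       params = params, tools = tools)
  }

  manifest <- list(
    package = "cvdscreen",
    version = as.character(utils::packageVersion("cvdscreen")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    n_population = nrow(population),
    n_scenarios = length(scenarios),
    base_scenario = base_ids,
    event_tool = event_tool,
    psa_draws = psa_draws,
    pill_disutility = pill_disutility,
    parameters = params[!vapply(params, is.data.frame, logical(1))]
  )
  result <- structure(
    list(population = population, scenarios = scenarios,
         screening = screening, cea = cea, frontier = frontier,
         dsa = dsa_res, pill = pill_res, psa = psa_res, manifest = manifest),
    class = "cvd_pipeline_result"
  )
  if (!is.null(outdir)) render_reports(result, outdir)
  result
}

#' Write tables, figures and the manifest for a pipeline result
#'
#' Produces a scenario-level CEA CSV (screening percentages, increments,
#' ICERs, dominance), the frontier CSV, an incremental cost-effectiveness
#' scatter with the frontier line, and — when the corresponding analyses
#' were run — the tornado table/plot and CEAC table/plot. Rendering is
#' deterministic given the result object.
#'
#' @param result A `cvd_pipeline_result`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
render_reports <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  tab <- merge(result$screening, as.data.frame(result$cea),
               by = "scenario_id", sort = TRUE)
  wr(tab, "cea_table.csv")
  wr(as.data.frame(result$frontier), "frontier.csv")

  cea <- as.data.frame(result$cea)
  fr <- as.data.frame(result$frontier)
  p <- ggplot2::ggplot(cea, ggplot2::aes(x = d_qaly, y = d_cost / 1e6)) +
    ggplot2::geom_point(ggplot2::aes(shape = on_frontier)) +
    ggplot2::geom_line(data = fr, colour = "grey40") +
    ggplot2::labs(x = "Incremental QALYs vs base case",
                  y = "Incremental cost (million USD)",
                  shape = "On frontier") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(outdir, "frontier.pdf"), p,
                  width = 7, height = 5)
  files <- c(files, file.path(outdir, "frontier.pdf"))

  if (!is.null(result$dsa)) {
    wr(result$dsa, "dsa_tornado.csv")
    base_icer <- result$dsa$icer[result$dsa$variation == "base"]
    dd <- result$dsa[result$dsa$variation != "base", ]
    p2 <- ggplot2::ggplot(dd, ggplot2::aes(x = icer,
                                           y = stats::reorder(variation,
                                                              abs(icer - base_icer)))) +
      ggplot2::geom_col() +
      ggplot2::geom_vline(xintercept = base_icer, linetype = 2) +
      ggplot2::labs(x = "ICER (USD/QALY)", y = NULL) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(outdir, "dsa_tornado.pdf"), p2,
                    width = 7, height = 5)
    files <- c(files, file.path(outdir, "dsa_tornado.pdf"))
  } else {
    notify("no deterministic sensitivity results; tornado outputs skipped")
  }
  if (!is.null(result$pill)) wr(result$pill, "pill_disutility.csv")
  if (!is.null(result$psa)) {
    wr(result$psa$ceac, "ceac.csv")
    wr(result$psa$draws, "psa_draws.csv")
    p3 <- ggplot2::ggplot(result$psa$ceac,
                          ggplot2::aes(wtp, probability,
                                       colour = scenario_id)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                    y = "Probability cost-effective") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(outdir, "ceac.pdf"), p3, width = 7, height = 5)
    files <- c(files, file.path(outdir, "ceac.pdf"))
  } else {
    notify("no probabilistic sensitivity results; CEAC outputs skipped")
  }
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(c(result$manifest, list(outputs = basename(files))),
                       manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  files <- c(files, manifest_path)
  invisible(files)
}

#' @export
print.cvd_pipeline_result <- function(x, ...) {
  cat("CVD screening cost-effectiveness pipeline result\n")
  cat("  population:", nrow(x$population), "persons\n")
  cat("  scenarios:", length(x$scenarios), "\n")
  cat("  frontier:", paste(x$frontier$scenario_id, collapse = " -> "), "\n")
  invisible(x)
}
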