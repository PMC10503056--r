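# Parameter uncertainty.
#
# Each uncertain parameter carries a sampling distribution reconstructed
# from its published point value and 95% CI: uniform +/- x%, log-normal
# fitted to the CI on the log scale (divisor 2 * 1.959964), beta matched to
# mean and CI-implied SD, or gamma from mean and a relative SD.
# Disutilities declared log-normal are sampled on the negated scale with an
# optional location shift so that a CI crossing zero stays inside the
# log-normal support.

Z95 <- 2 * stats::qnorm(0.975) # 2 x 1.959964

#' Declare a parameter sampling distribution
#'
#' @param name Parameter name (must exist in the parameter set).
#' @param family One of `"point"`, `"uniform_pct"`, `"lognormal_from_ci"`,
#'   `"beta_from_ci"`, `"gamma_mean_sd"`, `"lognormal_disutility"`.
#' @param value Point value.
#' @param pct Half-width as a fraction of the value (`uniform_pct`).
#' @param lo,hi 95% CI bounds (CI-based families).
#' @param sd_frac SD as a fraction of the mean (`gamma_mean_sd`).
#' @param shift Location shift for `lognormal_disutility` (sampled scale is
#'   `shift - value`; required > `hi`).
#' @return Object of class `parameter_distribution`.
#' @export
parameter_distribution <- function(name, family, value, pct = NULL, lo = NULL,
                                   hi = NULL, sd_frac = NULL, shift = 0) {
  family <- match.arg(family, c("point", "uniform_pct", "lognormal_from_ci",
                                "beta_from_ci", "gamma_mean_sd",
                                "lognormal_disutility"))
  if (!is.null(lo) && !is.null(hi) && lo >= hi) {
    stop_input("CI bounds must satisfy lo < hi for ", name)
  }
  if (family == "uniform_pct" && (is.null(pct) || pct < 0)) {
    stop_input("uniform_pct needs a non-negative pct for ", name)
  }
  if (family == "beta_from_ci") {
    s <- (hi - lo) / Z95
    if (s^2 >= value * (1 - value)) {
      stop_input("beta moment match infeasible for ", name,
                 " (sd too large for mean ", value, ")")
    }
  }
  if (family == "lognormal_disutility" && shift <= hi) {
    stop_input("lognormal_disutility shift must exceed the upper CI bound for ",
               name)
  }
  structure(list(name = name, family = family, value = value, pct = pct,
                 lo = lo, hi = hi, sd_frac = sd_frac, shift = shift),
            class = "parameter_distribution")
}

#' Sample from a parameter distribution
#'
#' Uses the current RNG stream; seed externally for reproducibility.
#'
#' @param dist A [parameter_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_distribution <- function(dist, n = 1) {
  v <- dist$value
  switch(dist$family,
    point = rep(v, n),
    uniform_pct = stats::runif(n, v * (1 - dist$pct), v * (1 + dist$pct)),
    lognormal_from_ci = {
      sdlog <- (log(dist$hi) - log(dist$lo)) / Z95
      stats::rlnorm(n, meanlog = log(v), sdlog = sdlog)
    },
    beta_from_ci = {
      s <- (dist$hi - dist$lo) / Z95
      nu <- v * (1 - v) / s^2 - 1
      stats::rbeta(n, shape1 = v * nu, shape2 = (1 - v) * nu)
    },
    gamma_mean_sd = {
      f <- dist$sd_frac
      stats::rgamma(n, shape = 1 / f^2, scale = v * f^2)
    },
    lognormal_disutility = {
      ## sample y = shift - x on the positive scale, return x = shift - y
      sdlog <- (log(dist$shift - dist$lo) - log(dist$shift - dist$hi)) / Z95
      y <- stats::rlnorm(n, meanlog = log(dist$shift - v), sdlog = sdlog)
      dist$shift - y
    }
  )
}

#' Default sampling distributions for the uncertain parameters
#'
#' One entry per uncertain model input: post-event mortality (beta from CI
#' for CHD, uniform +/- 20% for stroke), case-fatality scale (uniform
#' +/- 10%), the eight treatment relative risks (log-normal from their CIs),
#' unit costs (uniform +/- 10% or gamma with 10% relative SD), usual-care
#' inflation ratios (uniform +/- 20% for the general ratio, log-normal from
#' CI otherwise), event admission costs (uniform +/- 10%) and the three
#' disutilities (log-normal on the negated scale; the non-fatal-MI CI
#' crosses zero and uses a 0.05 location shift).
#'
#' @return Named list of [parameter_distribution()] objects.
#' @export
default_parameter_distributions <- function() {
  pd <- parameter_distribution
  dists <- list(
    pd("p_death_post_chd", "beta_from_ci", 0.03, lo = 0.01, hi = 0.04),
    pd("p_death_post_stroke", "uniform_pct", 0.10, pct = 0.20),
    pd("case_fatality_scale", "uniform_pct", 1.00, pct = 0.10),
    pd("rr_statin_nonfatal_mi", "lognormal_from_ci", 0.74, lo = 0.67, hi = 0.81),
    pd("rr_statin_nonfatal_stroke", "lognormal_from_ci", 0.86, lo = 0.78, hi = 0.95),
    pd("rr_statin_fatal_mi", "lognormal_from_ci", 0.82, lo = 0.75, hi = 0.91),
    pd("rr_statin_fatal_stroke", "lognormal_from_ci", 0.92, lo = 0.80, hi = 1.07),
    pd("rr_antihyp_nonfatal_mi", "lognormal_from_ci", 0.86, lo = 0.76, hi = 0.96),
    pd("rr_antihyp_nonfatal_stroke", "lognormal_from_ci", 0.86, lo = 0.72, hi = 1.01),
    pd("rr_antihyp_fatal_mi", "lognormal_from_ci", 0.86, lo = 0.65, hi = 1.14),
    pd("rr_antihyp_fatal_stroke", "lognormal_from_ci", 0.86, lo = 0.65, hi = 1.14),
    pd("cost_statin", "uniform_pct", 3.98, pct = 0.10),
    pd("cost_enalapril", "gamma_mean_sd", 2.21, sd_frac = 0.10),
    pd("cost_nifedipine", "gamma_mean_sd", 0.78, sd_frac = 0.10),
    pd("cost_metformin", "gamma_mean_sd", 6.27, sd_frac = 0.10),
    pd("cost_glucose_test", "gamma_mean_sd", 0.17, sd_frac = 0.10),
    pd("cost_cholesterol_test", "gamma_mean_sd", 0.19, sd_frac = 0.10),
    pd("cost_consultation", "gamma_mean_sd", 1.96, sd_frac = 0.10),
    pd("ratio_general", "uniform_pct", 1.00, pct = 0.20),
    pd("ratio_inpatient_chd", "lognormal_from_ci", 2.85, lo = 1.79, hi = 4.54),
    pd("ratio_inpatient_stroke", "lognormal_from_ci", 1.09, lo = 0.53, hi = 2.26),
    pd("ratio_outpatient_chd", "lognormal_from_ci", 1.95, lo = 1.45, hi = 2.61),
    pd("ratio_outpatient_stroke", "lognormal_from_ci", 1.97, lo = 0.83, hi = 4.69),
    pd("cost_mi_admission", "uniform_pct", 318, pct = 0.10),
    pd("cost_stroke_admission", "uniform_pct", 241, pct = 0.10),
    pd("disutility_nonfatal_mi", "lognormal_disutility", -0.0210,
       lo = -0.066, hi = 0.024, shift = 0.05),
    pd("disutility_nonfatal_stroke", "lognormal_disutility", -0.2493,
       lo = -0.340, hi = -0.158, shift = 0),
    pd("disutility_age_year", "lognormal_disutility", -0.0066,
       lo = -0.007, hi = -0.006, shift = 0)
  )
  names(dists) <- vapply(dists, `[[`, character(1), "name")
  dists
}

#' Draw one parameter-set realisation
#'
#' @param distributions Named list of [parameter_distribution()]s.
#' @param params Base `parameter_set` to overwrite.
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (as inside a PSA loop).
#' @return A `parameter_set` with one draw per distribution applied.
#' @export
draw_parameters <- function(distributions, params = default_parameters(),
                            seed = NULL) {
  dist_names <- vapply(distributions, `[[`, character(1), "name")
  unknown <- setdiff(dist_names, names(params))
  if (length(unknown)) {
    stop_input("distributions name unknown parameter(s): ",
               paste(unknown, collapse = ", "))
  }
  draw_all <- function() {
    for (d in distributions) params[[d$name]] <- draw_distribution(d, 1L)
    params
  }
  if (is.null(seed)) draw_all() else with_preserved_rng(seed, draw_all())
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the scenario-versus-base comparison once per named override set
#' and tabulates the resulting ICERs (tornado table input).
#'
#' @param population Validated population.
#' @param scenario,base_scenario `scenario_spec`s to compare.
#' @param overrides Named list; each element is itself a named list of
#'   parameter replacements (several parameters may move together).
#' @param params Base `parameter_set`.
#' @param tools Risk-tool registry.
#' @return `data.frame` with columns `variation`, `d_cost`, `d_qaly`,
#'   `icer`, `label`; the first row (`"base"`) is the unmodified comparison.
#' @export
one_way <- function(population, scenario, base_scenario, overrides = list(),
                    params = default_parameters(), tools = default_risk_tools()) {
  for (ov in overrides) {
    unknown <- setdiff(names(ov), names(params))
    if (length(unknown)) {
      stop_input("override names unknown parameter(s): ",
                 paste(unknown, collapse = ", "))
    }
  }
  risks <- event_risk_probabilities(population, tools)
  prep_alt <- prepare_scenario(population, scenario, tools)
  prep_base <- prepare_scenario(population, base_scenario, tools)
  run_once <- function(p) {
    inc <- incremental(evaluate_prepared(prep_base, population, risks, p),
                       evaluate_prepared(prep_alt, population, risks, p))
    data.frame(d_cost = inc$d_cost, d_qaly = inc$d_qaly, icer = inc$icer,
               label = inc$label, stringsAsFactors = FALSE)
  }
  rows <- list(cbind(variation = "base", run_once(params)))
  for (nm in names(overrides)) {
    p <- do.call(update_parameters, c(list(params), overrides[[nm]]))
    rows[[length(rows) + 1L]] <- cbind(variation = nm, run_once(p))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default one-way variations
#'
#' The standard deterministic variations: stronger antihypertensive effect
#' on non-fatal stroke (the higher-baseline-SBP estimate), discounting at 0%
#' and 6%, deepening the MI disutility to the stroke value, usual care at
#' 80% and 120%, and usual-care inflation ratios forced to 1 and 3.
#' @return Named list of override lists for [one_way()].
#' @export
default_one_way_variations <- function() {
  list(
    antihyp_stroke_strong = list(rr_antihyp_nonfatal_stroke = 0.72),
    discount_0 = list(discount_rate = 0),
    discount_6 = list(discount_rate = 0.06),
    mi_disutility_as_stroke = list(disutility_nonfatal_mi = -0.2493),
    usual_care_80 = list(usual_care_inpatient = 25 * 0.8,
                         usual_care_outpatient = 35 * 0.8),
    usual_care_120 = list(usual_care_inpatient = 25 * 1.2,
                          usual_care_outpatient = 35 * 1.2),
    cvd_care_ratio_1 = list(ratio_inpatient_chd = 1, ratio_inpatient_stroke = 1,
                            ratio_outpatient_chd = 1, ratio_outpatient_stroke = 1),
    cvd_care_ratio_3 = list(ratio_inpatient_chd = 3, ratio_inpatient_stroke = 3,
                            ratio_outpatient_chd = 3, ratio_outpatient_stroke = 3)
  )
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_draws` parameter-set realisations (common random parameters
#' across scenarios within a draw), re-evaluates every scenario and the base
#' case per draw, and summarises: a cost-effectiveness acceptability curve
#' (probability each scenario maximises net monetary benefit, ties splitting
#' the probability mass equally) over a willingness-to-pay grid, and the
#' per-scenario probability that the ICER versus base is at or below a
#' stated threshold (cost-saving draws count as below).
#'
#' @param population Validated population.
#' @param scenarios List of `scenario_spec`s (the comparator may be among
#'   them).
#' @param base_scenario Comparator `scenario_spec`.
#' @param distributions Parameter distributions (see
#'   [default_parameter_distributions()]).
#' @param n_draws Number of simulations (default 1000).
#' @param seed Root seed for the draws.
#' @param wtp_grid Willingness-to-pay values (USD/QALY); default 0 to 2x GDP
#'   per capita in 41 steps.
#' @param icer_threshold Threshold for the ICER probability (default 0.5x
#'   GDP per capita).
#' @param params Base `parameter_set`.
#' @param tools Risk-tool registry.
#' @return List of class `psa_result`: `draws` (long `data.frame` of
#'   per-draw program cost/QALYs per scenario), `ceac` (`data.frame` wtp x
#'   scenario probability), `icer_below_threshold` (named vector),
#'   `icer_threshold`, `seed`.
#' @export
run_psa <- function(population, scenarios, base_scenario,
                    distributions = default_parameter_distributions(),
                    n_draws = 1000, seed = 1,
                    wtp_grid = NULL, icer_threshold = 0.5 * 4083,
                    params = default_parameters(),
                    tools = default_risk_tools()) {
  if (n_draws < 1) stop_input("n_draws must be at least 1")
  if (is.null(wtp_grid)) {
    wtp_grid <- seq(0, 2 * params$gdp_per_capita, length.out = 41)
  }
  if (is.null(names(scenarios))) {
    names(scenarios) <- vapply(scenarios, `[[`, character(1), "scenario_id")
  }
  risks <- event_risk_probabilities(population, tools)
  preps <- lapply(scenarios, prepare_scenario, population = population,
                  tools = tools)
  prep_base <- prepare_scenario(population, base_scenario, tools)
  ids <- names(scenarios)
  ns <- length(ids)

  cost <- matrix(NA_real_, n_draws, ns, dimnames = list(NULL, ids))
  qaly <- cost
  cost_base <- qaly_base <- numeric(n_draws)
  all_preps <- c(preps, list(prep_base))
  with_preserved_rng(seed, {
    for (d in seq_len(n_draws)) {
      p_d <- draw_parameters(distributions, params, seed = NULL)
      ucache <- untreated_cache_by_rule(all_preps, risks, p_d)
      tb <- evaluate_prepared(prep_base, population, risks, p_d,
                              untreated = ucache[[prep_base$scenario$age_rule]])
      cost_base[d] <- tb$total_cost
      qaly_base[d] <- tb$total_qalys
      for (j in seq_len(ns)) {
        tj <- evaluate_prepared(preps[[j]], population, risks, p_d,
                                untreated = ucache[[preps[[j]]$scenario$age_rule]])
        cost[d, j] <- tj$total_cost
        qaly[d, j] <- tj$total_qalys
      }
    }
  })

  ## CEAC by net monetary benefit argmax, ties split equally
  ceac <- matrix(0, length(wtp_grid), ns,
                 dimnames = list(NULL, ids))
  for (w in seq_along(wtp_grid)) {
    nmb <- wtp_grid[w] * qaly - cost
    for (d in seq_len(n_draws)) {
      best <- which(nmb[d, ] == max(nmb[d, ]))
      ceac[w, best] <- ceac[w, best] + 1 / (n_draws * length(best))
    }
  }
  ceac_df <- data.frame(wtp = rep(wtp_grid, ns),
                        scenario_id = rep(ids, each = length(wtp_grid)),
                        probability = as.vector(ceac))

  d_cost <- cost - cost_base
  d_qaly <- qaly - qaly_base
  below <- d_cost < 0 | (d_qaly > 0 & d_cost / d_qaly <= icer_threshold)
  p_below <- colMeans(below)

  draws_df <- data.frame(
    draw = rep(seq_len(n_draws), ns + 1L),
    scenario_id = rep(c("base", ids), each = n_draws),
    cost = c(cost_base, as.vector(cost)),
    qalys = c(qaly_base, as.vector(qaly))
  )
  structure(list(draws = draws_df, ceac = ceac_df,
                 icer_below_threshold = p_below,
                 icer_threshold = icer_threshold, wtp_grid = wtp_grid,
                 seed = seed),
            class = "psa_result")
}

#' Pill-disutility sensitivity analysis
#'
#' Re-runs the scenario comparisons with a utility decrement applied to
#' every person newly started on any medication and reports the ICER shift
#' per scenario.
#'
#' @param population Validated population.
#' @param scenarios Named list of `scenario_spec`s.
#' @param base_scenario Comparator `scenario_spec`.
#' @param disutility Annual utility decrement (default 0.00384).
#' @param params Base `parameter_set` (its `pill_disutility` is overridden
#'   with 0 and with `disutility`).
#' @param tools Risk-tool registry.
#' @return `data.frame` per scenario: `d_qaly_without`, `d_qaly_with`,
#'   `icer_without`, `icer_with`, `icer_change`.
#' @export
pill_disutility_analysis <- function(population, scenarios, base_scenario,
                                     disutility = 0.00384,
                                     params = default_parameters(),
                                     tools = default_risk_tools()) {
  if (disutility < 0) stop_input("disutility must be non-negative")
  if (is.null(names(scenarios))) {
    names(scenarios) <- vapply(scenarios, `[[`, character(1), "scenario_id")
  }
  risks <- event_risk_probabilities(population, tools)
  prep_base <- prepare_scenario(population, base_scenario, tools)
  run_with <- function(pill) {
    p <- update_parameters(params, pill_disutility = pill)
    tb <- evaluate_prepared(prep_base, population, risks, p)
    lapply(scenarios, function(sc) {
      incremental(tb, evaluate_prepared(
        prepare_scenario(population, sc, tools), population, risks, p))
    })
  }
  without <- run_with(0)
  with_p <- run_with(disutility)
  out <- do.call(rbind, lapply(names(scenarios), function(id) {
    data.frame(scenario_id = id,
               d_qaly_without = without[[id]]$d_qaly,
               d_qaly_with = with_p[[id]]$d_qaly,
               icer_without = without[[id]]$icer,
               icer_with = with_p[[id]]$icer,
               icer_change = with_p[[id]]$icer - without[[id]]$icer,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
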