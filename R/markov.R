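# Lifetime five-state Markov cohort engine.
#
# States: NO_CVD, POST_CHD, POST_STROKE, DEAD_CVD, DEAD_OTHER (both dead
# states absorbing). Each screened individual is propagated as an
# expected-value occupancy distribution (initial mass 1 on NO_CVD) with
# 1-year cycles until death certainty or age 100. Events (CHD, stroke) occur
# only in cycles 1-10; incident events split into fatal and non-fatal parts
# by the case-fatality table; treatment relative risks apply over the
# 10-year effect horizon and compose multiplicatively across medication
# classes; after cycle 10 every alive state faces background mortality only.
# QALY and recurring cost flows are half-cycle corrected (valued at the mean
# of start- and end-of-cycle occupancy) and discounted at 1/(1+r)^t; one-off
# event admission and screening costs are not half-cycle corrected.

STATES <- c("NO_CVD", "POST_CHD", "POST_STROKE", "DEAD_CVD", "DEAD_OTHER")

#' Apply treatment effects to annual event probabilities
#'
#' Within the treatment-effect horizon each probability is multiplied by the
#' relative risk of every medication class the person takes that targets the
#' outcome (statins and antihypertensives compose multiplicatively); outside
#' the horizon probabilities are returned unchanged. Outputs are clamped to
#' `[0, 1]`.
#'
#' @param p_fatal,p_nonfatal Annual probabilities (vectorised over persons).
#' @param condition `"chd"` or `"stroke"`.
#' @param plan Treatment-plan `data.frame` with logical `statin` and
#'   `antihypertensive` columns.
#' @param params A `parameter_set`.
#' @param cycle_index Cycle number (1-based).
#' @return List with adjusted `p_fatal` and `p_nonfatal`.
#' @export
apply_treatment_effects <- function(p_fatal, p_nonfatal, condition, plan,
                                    params, cycle_index) {
  if (cycle_index > params$effect_horizon) {
    return(list(p_fatal = p_fatal, p_nonfatal = p_nonfatal))
  }
  st <- as.numeric(plan$statin)
  ah <- as.numeric(plan$antihypertensive)
  if (condition == "chd") {
    rr_f <- params$rr_statin_fatal_mi^st * params$rr_antihyp_fatal_mi^ah
    rr_nf <- params$rr_statin_nonfatal_mi^st * params$rr_antihyp_nonfatal_mi^ah
  } else {
    rr_f <- params$rr_statin_fatal_stroke^st * params$rr_antihyp_fatal_stroke^ah
    rr_nf <- params$rr_statin_nonfatal_stroke^st *
      params$rr_antihyp_nonfatal_stroke^ah
  }
  list(p_fatal = clamp(p_fatal * rr_f, 0, 1),
       p_nonfatal = clamp(p_nonfatal * rr_nf, 0, 1))
}

## Per-cycle transition ingredients for every person: event splits after
## treatment effects, background mortality, and post-event death
## probabilities with their destination state. Shared by the cohort engine
## and transition_matrix() so the two can never disagree.
cycle_rates <- function(individuals, ages, plan, params, cycle_index,
                        p1_chd, p1_stroke) {
  q <- life_table_q(params$life_table, ages, individuals$sex)
  in_event_window <- cycle_index <= params$event_horizon
  if (in_event_window) {
    sc <- clamp(params$case_fatality_scale, 0, Inf)
    sp_c <- split_fatal_nonfatal(p1_chd, "chd", ages, individuals$sex,
                                 params$case_fatality)
    f_chd <- clamp(sp_c$p_fatal * sc, 0, p1_chd)
    sp_c <- list(p_fatal = f_chd, p_nonfatal = p1_chd - f_chd)
    sp_s <- split_fatal_nonfatal(p1_stroke, "stroke", ages, individuals$sex,
                                 params$case_fatality)
    f_str <- clamp(sp_s$p_fatal * sc, 0, p1_stroke)
    sp_s <- list(p_fatal = f_str, p_nonfatal = p1_stroke - f_str)
    sp_c <- apply_treatment_effects(sp_c$p_fatal, sp_c$p_nonfatal, "chd",
                                    plan, params, cycle_index)
    sp_s <- apply_treatment_effects(sp_s$p_fatal, sp_s$p_nonfatal, "stroke",
                                    plan, params, cycle_index)
    post_chd_death <- pmax(params$p_death_post_chd, q)
    post_stroke_death <- pmax(params$p_death_post_stroke, q)
    post_death_to_cvd <- TRUE
  } else {
    zero <- numeric(length(ages))
    sp_c <- list(p_fatal = zero, p_nonfatal = zero)
    sp_s <- list(p_fatal = zero, p_nonfatal = zero)
    post_chd_death <- q
    post_stroke_death <- q
    post_death_to_cvd <- FALSE
  }
  total_event <- clamp(sp_c$p_fatal + sp_c$p_nonfatal +
                         sp_s$p_fatal + sp_s$p_nonfatal, 0, 1)
  list(q = q, chd_fatal = sp_c$p_fatal, chd_nonfatal = sp_c$p_nonfatal,
       stroke_fatal = sp_s$p_fatal, stroke_nonfatal = sp_s$p_nonfatal,
       total_event = total_event,
       post_chd_death = post_chd_death,
       post_stroke_death = post_stroke_death,
       post_death_to_cvd = post_death_to_cvd)
}

#' Single-cycle transition matrix for one individual
#'
#' Builds the 5x5 transition matrix over `NO_CVD`, `POST_CHD`,
#' `POST_STROKE`, `DEAD_CVD`, `DEAD_OTHER` for the given cycle. Competing
#' risks in the `NO_CVD` row: background mortality applies to the event-free
#' remainder (`q * (1 - p_events)`). Post-event states face the post-event
#' death probabilities (floored at background mortality, attributed to CVD
#' death) within the first 10 cycles and background mortality only
#' (attributed to non-CVD death) thereafter. Rows sum to 1.
#'
#' @param individual One-row population slice.
#' @param age Age during this cycle.
#' @param plan One-row treatment plan.
#' @param params A `parameter_set`.
#' @param cycle_index 1-based cycle number.
#' @param p1_chd,p1_stroke Untreated annual event probabilities (ground
#'   truth).
#' @return 5x5 matrix with `STATES` dimnames.
#' @export
transition_matrix <- function(individual, age, plan, params, cycle_index,
                              p1_chd, p1_stroke) {
  if (age > params$max_age) stop_input("age exceeds the model's maximum age")
  r <- cycle_rates(individual, age, plan, params, cycle_index, p1_chd, p1_stroke)
  M <- matrix(0, 5, 5, dimnames = list(STATES, STATES))
  to_dead_other <- r$q * (1 - r$total_event)
  M[1, ] <- c(1 - r$total_event - to_dead_other, r$chd_nonfatal,
              r$stroke_nonfatal, r$chd_fatal + r$stroke_fatal, to_dead_other)
  dest <- if (r$post_death_to_cvd) 4L else 5L
  M[2, 2] <- 1 - r$post_chd_death
  M[2, dest] <- r$post_chd_death
  M[3, 3] <- 1 - r$post_stroke_death
  M[3, dest] <- r$post_stroke_death
  M[4, 4] <- 1
  M[5, 5] <- 1
  M
}

#' Annual utility by state
#'
#' `baseline_utility + years_since_baseline * age decrement + state
#' decrement - pill disutility` (the latter only for persons newly started
#' on any medication), floored at the configured minimum.
#'
#' @param individuals Population rows.
#' @param state One of `"NO_CVD"`, `"POST_CHD"`, `"POST_STROKE"`.
#' @param years_since_baseline Whole years elapsed since screening (0 in the
#'   first cycle).
#' @param plan Treatment plans for the same rows.
#' @param params A `parameter_set`.
#' @return Annual utility vector.
#' @export
utility_flow <- function(individuals, state, years_since_baseline, plan, params) {
  dec <- switch(state,
    NO_CVD = 0,
    POST_CHD = params$disutility_nonfatal_mi,
    POST_STROKE = params$disutility_nonfatal_stroke,
    stop_input("utility_flow applies to alive states only")
  )
  u <- individuals$baseline_utility +
    years_since_baseline * params$disutility_age_year + dec -
    params$pill_disutility * as.numeric(plan$newly_started_any)
  pmax(u, params$utility_floor)
}

#' Annual recurring cost by state
#'
#' Medication costs for every class taken (antihypertensive regimen =
#' enalapril + nifedipine), follow-up consultations and tests per the plan's
#' schedule (initial-year versus subsequent-year rates), and usual-care cost
#' (base inpatient/outpatient costs scaled by the state-specific inflation
#' ratios; ratio 1 for `NO_CVD`). One-off event admission and screening
#' costs are accounted by the engine, not here.
#'
#' @inheritParams utility_flow
#' @param cycle_index 1-based cycle number (cycle 1 uses the initial-year
#'   follow-up rate).
#' @return Annual cost vector (USD).
#' @export
cost_flow <- function(individuals, state, cycle_index, plan, params) {
  med <- params$cost_statin * plan$statin +
    (params$cost_enalapril + params$cost_nifedipine) * plan$antihypertensive +
    params$cost_metformin * plan$hypoglycaemic
  visits <- if (cycle_index == 1) plan$follow_ups_initial_year else
    plan$follow_ups_subsequent_years
  fu <- visits * params$cost_consultation +
    plan$glucose_tests_per_year * params$cost_glucose_test +
    plan$cholesterol_tests_per_year * params$cost_cholesterol_test
  uc <- switch(state,
    NO_CVD = (params$usual_care_inpatient + params$usual_care_outpatient) *
      params$ratio_general,
    POST_CHD = params$usual_care_inpatient * params$ratio_inpatient_chd +
      params$usual_care_outpatient * params$ratio_outpatient_chd,
    POST_STROKE = params$usual_care_inpatient * params$ratio_inpatient_stroke +
      params$usual_care_outpatient * params$ratio_outpatient_stroke,
    stop_input("cost_flow applies to alive states only")
  )
  med + fu + uc
}

#' Simulate a screened cohort through the lifetime Markov model
#'
#' Vectorised expected-value propagation of every person's occupancy
#' distribution, accumulating half-cycle-corrected discounted and
#' undiscounted QALYs and costs, expected event counts and life years.
#'
#' @param individuals Screened population rows (`age`, `sex`,
#'   `baseline_utility` used).
#' @param plan Treatment plans for the same rows ([assign_treatments()]).
#' @param params A `parameter_set`.
#' @param p1_chd,p1_stroke Untreated annual event probabilities per person
#'   (ground-truth tool, annualised).
#' @param mode `"office"` or `"lab"`; lab adds the cholesterol test to the
#'   one-off screening cost.
#' @param include_screening_cost Add the year-0 screening visit cost
#'   (consultation + glucose test + cholesterol test in lab mode).
#' @param trace Also return the full occupancy array (persons x states x
#'   cycle starts); intended for diagnostics on small cohorts.
#' @return `data.frame` with one row per person: `disc_qalys`, `disc_costs`,
#'   `undisc_qalys`, `undisc_costs`, `life_years`, expected event counts
#'   (`events_chd_nonfatal`, `events_chd_fatal`, `events_stroke_nonfatal`,
#'   `events_stroke_fatal`). With `trace = TRUE`, a list
#'   `(outcomes, occupancy)`.
#' @export
simulate_cohort <- function(individuals, plan, params, p1_chd, p1_stroke,
                            mode = "office", include_screening_cost = TRUE,
                            trace = FALSE) {
  n <- nrow(individuals)
  stopifnot(nrow(plan) == n, length(p1_chd) == n, length(p1_stroke) == n)
  r <- params$discount_rate
  age0 <- floor(individuals$age)
  horizon <- pmax(params$max_age - age0, 0L)
  T_max <- if (n) max(horizon) else 0L

  occ <- matrix(0, n, 5)
  occ[, 1] <- 1
  disc_q <- undisc_q <- disc_c <- undisc_c <- numeric(n)
  life_years <- numeric(n)
  ev <- matrix(0, n, 4,
               dimnames = list(NULL, c("chd_nonfatal", "chd_fatal",
                                       "stroke_nonfatal", "stroke_fatal")))
  if (include_screening_cost && n) {
    screen_cost <- params$cost_consultation + params$cost_glucose_test +
      if (identical(mode, "lab")) params$cost_cholesterol_test else 0
    disc_c <- disc_c + screen_cost
    undisc_c <- undisc_c + screen_cost
  }
  occ_trace <- if (trace) array(NA_real_, c(n, 5, T_max + 1L)) else NULL
  if (trace && T_max >= 0) occ_trace[, , 1L] <- occ

  for (t in seq_len(T_max)) {
    active <- t <= horizon
    if (!any(active)) break
    ages_t <- age0 + t - 1L
    ## uncovered ages can only belong to inactive persons; pin them inside
    ages_t[!active] <- age0[!active]
    rt <- cycle_rates(individuals, ages_t, plan, params, t, p1_chd, p1_stroke)

    to_dother_from_nocvd <- rt$q * (1 - rt$total_event)
    stay_nocvd <- 1 - rt$total_event - to_dother_from_nocvd
    dest_cvd <- rt$post_death_to_cvd

    occ_new <- occ
    occ_new[, 1] <- occ[, 1] * stay_nocvd
    occ_new[, 2] <- occ[, 2] * (1 - rt$post_chd_death) + occ[, 1] * rt$chd_nonfatal
    occ_new[, 3] <- occ[, 3] * (1 - rt$post_stroke_death) +
      occ[, 1] * rt$stroke_nonfatal
    post_deaths <- occ[, 2] * rt$post_chd_death + occ[, 3] * rt$post_stroke_death
    occ_new[, 4] <- occ[, 4] + occ[, 1] * (rt$chd_fatal + rt$stroke_fatal) +
      if (dest_cvd) post_deaths else 0
    occ_new[, 5] <- occ[, 5] + occ[, 1] * to_dother_from_nocvd +
      if (dest_cvd) 0 else post_deaths
    ## frozen occupancy for persons past their horizon
    if (!all(active)) occ_new[!active, ] <- occ[!active, ]

    avg <- (occ + occ_new) / 2
    mask <- as.numeric(active)
    df <- (1 + r)^(-t)

    u1 <- utility_flow(individuals, "NO_CVD", t - 1L, plan, params)
    u2 <- utility_flow(individuals, "POST_CHD", t - 1L, plan, params)
    u3 <- utility_flow(individuals, "POST_STROKE", t - 1L, plan, params)
    q_flow <- (avg[, 1] * u1 + avg[, 2] * u2 + avg[, 3] * u3) * mask
    undisc_q <- undisc_q + q_flow
    disc_q <- disc_q + q_flow * df

    c1 <- cost_flow(individuals, "NO_CVD", t, plan, params)
    c2 <- cost_flow(individuals, "POST_CHD", t, plan, params)
    c3 <- cost_flow(individuals, "POST_STROKE", t, plan, params)
    inc_chd <- occ[, 1] * (rt$chd_nonfatal + rt$chd_fatal)
    inc_str <- occ[, 1] * (rt$stroke_nonfatal + rt$stroke_fatal)
    c_flow <- (avg[, 1] * c1 + avg[, 2] * c2 + avg[, 3] * c3 +
                 inc_chd * params$cost_mi_admission +
                 inc_str * params$cost_stroke_admission) * mask
    undisc_c <- undisc_c + c_flow
    disc_c <- disc_c + c_flow * df

    life_years <- life_years + (avg[, 1] + avg[, 2] + avg[, 3]) * mask
    ev[, "chd_nonfatal"] <- ev[, "chd_nonfatal"] + occ[, 1] * rt$chd_nonfatal * mask
    ev[, "chd_fatal"] <- ev[, "chd_fatal"] + occ[, 1] * rt$chd_fatal * mask
    ev[, "stroke_nonfatal"] <- ev[, "stroke_nonfatal"] +
      occ[, 1] * rt$stroke_nonfatal * mask
    ev[, "stroke_fatal"] <- ev[, "stroke_fatal"] + occ[, 1] * rt$stroke_fatal * mask

    occ <- occ_new
    if (trace) occ_trace[, , t + 1L] <- occ
  }

  outcomes <- data.frame(
    disc_qalys = disc_q, disc_costs = disc_c,
    undisc_qalys = undisc_q, undisc_costs = undisc_c,
    life_years = life_years,
    events_chd_nonfatal = ev[, "chd_nonfatal"],
    events_chd_fatal = ev[, "chd_fatal"],
    events_stroke_nonfatal = ev[, "stroke_nonfatal"],
    events_stroke_fatal = ev[, "stroke_fatal"]
  )
  if (trace) list(outcomes = outcomes, occupancy = occ_trace) else outcomes
}

#' Simulate one individual
#'
#' Convenience wrapper over [simulate_cohort()] for a single person.
#'
#' @inheritParams simulate_cohort
#' @param individual,plan One-row slices.
#' @return One-row outcomes `data.frame` (or a list with the occupancy trace
#'   when `trace = TRUE`).
#' @export
simulate_individual <- function(individual, plan, params, p1_chd, p1_stroke,
                                mode = "office", include_screening_cost = TRUE,
                                trace = FALSE) {
  simulate_cohort(individual, plan, params, p1_chd, p1_stroke, mode,
                  include_screening_cost, trace)
}

#' Untreated comparator plan
#'
#' A plan with every flag false and an empty follow-up schedule, used as the
#' no-intervention comparator in incremental checks.
#'
#' @param n Number of rows.
#' @return Treatment-plan `data.frame`.
#' @export
null_plan <- function(n) {
  data.frame(
    high_risk = rep(FALSE, n), antihypertensive = rep(FALSE, n),
    statin = rep(FALSE, n), hypoglycaemic = rep(FALSE, n),
    newly_started_any = rep(FALSE, n),
    follow_ups_initial_year = rep(0L, n),
    follow_ups_subsequent_years = rep(0L, n),
    glucose_tests_per_year = rep(0L, n),
    cholesterol_tests_per_year = rep(0L, n)
  )
}
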