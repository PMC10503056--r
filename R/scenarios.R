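# Screening and treatment policy.
#
# A scenario is one program design: which risk tool classifies people, which
# age group is screened, the high-risk threshold, and two optional policy
# flags (statins for all diabetics; a lowered blood-pressure treatment
# threshold for diabetics and high-risk people). Treatment rules follow the
# national screening guideline logic: BP >= 140/90 (OR over the two
# readings) for antihypertensives, fasting glucose >= 126 or random glucose
# >= 200 mg/dL for hypoglycaemics, total cholesterol >= 300 mg/dL (lab
# scenarios) or high CVD risk for statins.

#' Annual screening capacity of the clinic network
#'
#' @param patients_per_week Patients one clinic screens per week.
#' @param n_clinics Number of clinics.
#' @param weeks_per_year Operating weeks per year.
#' @param utilization Fraction of nominal capacity used.
#' @return Persons screened per program year (default 20 x 1000 x 48 x 0.70 =
#'   672,000).
#' @export
hlc_capacity <- function(patients_per_week = 20, n_clinics = 1000,
                         weeks_per_year = 48, utilization = 0.70) {
  patients_per_week * n_clinics * weeks_per_year * utilization
}

#' Specify one screening scenario
#'
#' @param scenario_id Unique identifier.
#' @param risk_tool Tool id used for high-risk classification.
#' @param mode `"office"` or `"lab"`; lab scenarios add cholesterol testing
#'   and the cholesterol-based statin rule.
#' @param age_rule `"35plus"`, `"40plus"` or `"40to65"`.
#' @param high_risk_threshold 10-year combined CVD risk at or above which a
#'   person is classified high risk; in (0, 1).
#' @param statins_all_diabetics Give statins to every diabetic regardless of
#'   risk or cholesterol.
#' @param lowered_bp_threshold Prescribe antihypertensives at 130/80 for
#'   diabetics and high-risk people.
#' @param capacity Persons screened per program year; see [hlc_capacity()].
#' @param base_case Marks the comparator scenario.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario_id, risk_tool, mode,
                          age_rule = c("35plus", "40plus", "40to65"),
                          high_risk_threshold = 0.20,
                          statins_all_diabetics = FALSE,
                          lowered_bp_threshold = FALSE,
                          capacity = hlc_capacity(),
                          base_case = FALSE) {
  age_rule <- match.arg(age_rule)
  mode <- match.arg(mode, c("office", "lab"))
  if (!(high_risk_threshold > 0 && high_risk_threshold < 1)) {
    stop_input("high_risk_threshold must lie in (0, 1)")
  }
  if (capacity <= 0) stop_input("capacity must be positive")
  structure(list(scenario_id = scenario_id, risk_tool = risk_tool,
                 mode = mode, age_rule = age_rule,
                 high_risk_threshold = high_risk_threshold,
                 statins_all_diabetics = statins_all_diabetics,
                 lowered_bp_threshold = lowered_bp_threshold,
                 capacity = capacity, base_case = base_case),
            class = "scenario_spec")
}

#' Build the scenario grid
#'
#' Cartesian product of tools, age rules, risk thresholds and the two policy
#' flags, plus one distinguished appended scenario (by default the previous
#' national protocol: first tool, 30% threshold, ages 40-65). The comparator
#' (base-case) scenario inside the product is flagged via `base_tool` /
#' `base_threshold` / `base_age_rule`. The default axes (8 tools x 2 ages x 2
#' thresholds x 2 x 2 + 1) give 129 scenarios.
#'
#' @param tools Character vector of `"tool_id:mode"` entries (or plain tool
#'   ids, in which case office mode is assumed).
#' @param age_rules,thresholds Axis values.
#' @param statins_all_diabetics,lowered_bp_threshold Axis values for the
#'   policy flags.
#' @param capacity Program capacity applied to every scenario.
#' @param extra_scenario The appended distinguished scenario
#'   (`scenario_spec` or `NULL` to omit).
#' @param base_tool,base_mode,base_threshold,base_age_rule Identify which
#'   product cell is the comparator.
#' @return List of `scenario_spec`, unique `scenario_id`s, exactly one
#'   scenario flagged `base_case` (when the comparator cell is on the grid).
#' @export
build_scenario_grid <- function(tools = default_tool_axis(),
                                age_rules = c("35plus", "40plus"),
                                thresholds = c(0.20, 0.10),
                                statins_all_diabetics = c(FALSE, TRUE),
                                lowered_bp_threshold = c(FALSE, TRUE),
                                capacity = hlc_capacity(),
                                extra_scenario = "previous_protocol",
                                base_tool = "who_ish", base_mode = "office",
                                base_threshold = 0.20,
                                base_age_rule = "35plus") {
  for (axis in list(tools, age_rules, thresholds, statins_all_diabetics,
                    lowered_bp_threshold)) {
    if (anyDuplicated(axis)) stop_input("duplicate axis values in scenario grid")
  }
  grid <- expand.grid(tool = tools, age_rule = age_rules,
                      threshold = thresholds, sd = statins_all_diabetics,
                      lbp = lowered_bp_threshold,
                      stringsAsFactors = FALSE)
  scenarios <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    tm <- parse_tool_axis(g$tool)
    is_base <- identical(tm$tool, base_tool) && identical(tm$mode, base_mode) &&
      g$threshold == base_threshold && g$age_rule == base_age_rule &&
      !g$sd && !g$lbp
    scenario_spec(
      scenario_id = sprintf("%s_%s_t%02d_%s%s%s", tm$tool, tm$mode,
                            round(100 * g$threshold), g$age_rule,
                            if (g$sd) "_sd" else "",
                            if (g$lbp) "_lbp" else ""),
      risk_tool = tm$tool, mode = tm$mode, age_rule = g$age_rule,
      high_risk_threshold = g$threshold, statins_all_diabetics = g$sd,
      lowered_bp_threshold = g$lbp, capacity = capacity, base_case = is_base
    )
  })
  if (identical(extra_scenario, "previous_protocol")) {
    tm <- parse_tool_axis(tools[[1]])
    extra_scenario <- scenario_spec(
      scenario_id = sprintf("%s_%s_t30_40to65", tm$tool, tm$mode),
      risk_tool = tm$tool, mode = tm$mode, age_rule = "40to65",
      high_risk_threshold = 0.30, capacity = capacity
    )
  }
  if (!is.null(extra_scenario)) scenarios <- c(scenarios, list(extra_scenario))
  ids <- vapply(scenarios, `[[`, character(1), "scenario_id")
  if (anyDuplicated(ids)) stop_input("scenario ids are not unique")
  names(scenarios) <- ids
  scenarios
}

default_tool_axis <- function() {
  c("who_ish:office", "who_ish:lab", "who2019:office", "who2019:lab",
    "framingham:office", "framingham:lab", "globorisk:office", "globorisk:lab")
}

parse_tool_axis <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  list(tool = parts[1], mode = if (length(parts) > 1) parts[2] else "office")
}

#' Screening eligibility
#'
#' A person is eligible when their age satisfies the scenario's age rule and
#' they have no prior CVD. Age intervals are inclusive of both stated bounds
#' (`40to65` means 40 <= age <= 65).
#'
#' @param individuals Population `data.frame`.
#' @param scenario A `scenario_spec`.
#' @return Logical vector.
#' @export
eligible <- function(individuals, scenario) {
  age_ok <- switch(scenario$age_rule,
    "35plus" = individuals$age >= 35,
    "40plus" = individuals$age >= 40,
    "40to65" = individuals$age >= 40 & individuals$age <= 65
  )
  age_ok & !individuals$prior_cvd
}

#' Assign treatments under a scenario
#'
#' Implements the guideline rules: high risk when the classification risk
#' reaches the scenario threshold; antihypertensives at BP >= 140/90 (either
#' reading), extended to 130/80 for diabetics and high-risk people when the
#' lowered-threshold flag is on; statins for high risk, lab-mode total
#' cholesterol >= 300 mg/dL, or (flag) all diabetics; hypoglycaemics at
#' fasting glucose >= 126 or random glucose >= 200 mg/dL, or for anyone
#' already flagged diabetic. Once started, medication continues for life.
#'
#' @param individuals Screened population rows.
#' @param scenario A `scenario_spec`.
#' @param p10_combined Combined 10-year CVD risk used for classification
#'   (from the scenario's own tool).
#' @return `data.frame` of per-person treatment plans (one row per input
#'   row): flags `high_risk`, `antihypertensive`, `statin`, `hypoglycaemic`,
#'   `newly_started_any` and the follow-up schedule counts.
#' @export
assign_treatments <- function(individuals, scenario, p10_combined) {
  high_risk <- p10_combined >= scenario$high_risk_threshold
  bp_standard <- individuals$sbp >= 140 | individuals$dbp >= 90
  bp_lowered <- scenario$lowered_bp_threshold &
    (individuals$diabetes | high_risk) &
    (individuals$sbp >= 130 | individuals$dbp >= 80)
  antihypertensive <- bp_standard | bp_lowered
  statin <- high_risk |
    (scenario$mode == "lab" & individuals$total_cholesterol >= 300) |
    (scenario$statins_all_diabetics & individuals$diabetes)
  hypoglycaemic <- individuals$fasting_glucose >= 126 |
    individuals$random_glucose >= 200 | individuals$diabetes
  plan <- data.frame(
    high_risk = high_risk, antihypertensive = antihypertensive,
    statin = statin, hypoglycaemic = hypoglycaemic,
    newly_started_any = antihypertensive | statin | hypoglycaemic,
    stringsAsFactors = FALSE
  )
  follow_up_schedule(plan, scenario)
}

#' Attach the follow-up and testing schedule to a treatment plan
#'
#' High-risk people: two follow-ups and two glucose tests per year (plus a
#' cholesterol test per visit in lab scenarios). Medicated non-high-risk
#' people: one follow-up and one glucose test per year, with one additional
#' follow-up in the initial year. Others: no follow-up.
#'
#' @param plan Treatment-plan `data.frame` (flags set).
#' @param scenario A `scenario_spec`.
#' @return `plan` with schedule columns `follow_ups_initial_year`,
#'   `follow_ups_subsequent_years`, `glucose_tests_per_year`,
#'   `cholesterol_tests_per_year`.
#' @export
follow_up_schedule <- function(plan, scenario) {
  medicated <- plan$antihypertensive | plan$statin | plan$hypoglycaemic
  tier2 <- !plan$high_risk & medicated
  plan$follow_ups_initial_year <- ifelse(plan$high_risk, 2L, ifelse(tier2, 2L, 0L))
  plan$follow_ups_subsequent_years <- ifelse(plan$high_risk, 2L, ifelse(tier2, 1L, 0L))
  plan$glucose_tests_per_year <- ifelse(plan$high_risk, 2L, ifelse(tier2, 1L, 0L))
  plan$cholesterol_tests_per_year <-
    ifelse(plan$high_risk & scenario$mode == "lab", 2L, 0L)
  plan
}

#' Screen a population under one scenario
#'
#' Applies eligibility, classifies risk with the scenario's own tool, assigns
#' treatment plans, and summarises weighted medication-commencement
#' percentages over the screened (eligible) persons.
#'
#' @param population Validated population `data.frame`.
#' @param scenario A `scenario_spec`.
#' @param tools Named list of risk tools (see [default_risk_tools()]).
#' @return List with `eligible` (logical over the population), `screened`
#'   (the eligible rows), `risk` (combined 10-year classification risk for
#'   screened rows), `plan` (treatment plans for screened rows) and
#'   `summary` (weighted percent of screened persons newly commenced per
#'   medication class and on at least one).
#' @export
screen_cohort <- function(population, scenario, tools = default_risk_tools()) {
  elig <- eligible(population, scenario)
  screened <- population[elig, , drop = FALSE]
  tool_key <- paste0(scenario$risk_tool, "_", scenario$mode)
  tool <- tools[[tool_key]]
  if (is.null(tool)) stop_input("unknown risk tool: ", tool_key)
  if (nrow(screened) == 0L) {
    notify("no eligible persons under scenario ", scenario$scenario_id)
    empty_plan <- follow_up_schedule(
      data.frame(high_risk = logical(0), antihypertensive = logical(0),
                 statin = logical(0), hypoglycaemic = logical(0),
                 newly_started_any = logical(0)), scenario)
    return(list(eligible = elig, screened = screened, risk = numeric(0),
                plan = empty_plan,
                summary = commencement_summary(empty_plan, numeric(0))))
  }
  risk <- predict_combined_risk(screened, tool)
  plan <- assign_treatments(screened, scenario, risk)
  list(eligible = elig, screened = screened, risk = risk, plan = plan,
       summary = commencement_summary(plan, screened$survey_weight))
}

commencement_summary <- function(plan, weights) {
  wpct <- function(flag) {
    if (!length(weights) || sum(weights) == 0) return(0)
    100 * sum(weights[flag]) / sum(weights)
  }
  data.frame(
    pct_antihypertensive = wpct(plan$antihypertensive),
    pct_statin = wpct(plan$statin),
    pct_hypoglycaemic = wpct(plan$hypoglycaemic),
    pct_any_medication = wpct(plan$newly_started_any),
    pct_high_risk = wpct(plan$high_risk)
  )
}
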