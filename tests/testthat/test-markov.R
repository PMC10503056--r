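test_that("treatment effects compose multiplicatively within the horizon", {
  params <- default_parameters()
  no_med <- null_plan(1)
  adj <- apply_treatment_effects(0.02, 0.10, "chd", no_med, params, 1)
  expect_equal(adj$p_nonfatal, 0.10)
  expect_equal(adj$p_fatal, 0.02)

  statin <- transform(null_plan(1), statin = TRUE)
  adj <- apply_treatment_effects(0, 0.10, "chd", statin, params, 5)
  expect_equal(adj$p_nonfatal, 0.074) # 0.10 x RR 0.74

  both <- transform(statin, antihypertensive = TRUE)
  adj <- apply_treatment_effects(0, 0.10, "chd", both, params, 5)
  expect_equal(adj$p_nonfatal, 0.10 * 0.74 * 0.86)

  # beyond the 10-year effect horizon probabilities pass through unchanged
  adj11 <- apply_treatment_effects(0.02, 0.10, "chd", both, params, 11)
  expect_equal(adj11$p_nonfatal, 0.10)
  expect_equal(adj11$p_fatal, 0.02)
})

test_that("transition rows sum to one and dead states are absorbing", {
  params <- default_parameters()
  plan <- transform(null_plan(1), statin = TRUE, antihypertensive = TRUE)
  person <- make_person(age = 60)
  for (cyc in c(1, 5, 10, 11, 30)) {
    M <- transition_matrix(person, 60 + cyc - 1, plan, params, cyc,
                           p1_chd = 0.012, p1_stroke = 0.008)
    expect_equal(rowSums(M), rep(1, 5), tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(M["DEAD_CVD", "DEAD_CVD"], 1)
    expect_equal(M["DEAD_OTHER", "DEAD_OTHER"], 1)
    expect_true(all(M >= 0 & M <= 1))
  }
})

test_that("degenerate transition inputs give the expected matrices", {
  qp <- quiet_params()
  person <- make_person(age = 60)
  # zero events and zero mortality: identity
  M <- transition_matrix(person, 60, null_plan(1), qp, 1, 0, 0)
  expect_equal(M, diag(5), ignore_attr = TRUE)
  # certain mortality after the event window: every alive state -> DEAD_OTHER
  lt1 <- make_life_table()
  lt1$q <- 1
  p1 <- default_parameters(life_table = lt1)
  M1 <- transition_matrix(person, 99, null_plan(1), p1, 11, 0, 0)
  expect_equal(unname(M1[1:3, 5]), rep(1, 3))
  # NO_CVD row with a 0.012/0.028 CHD split and background mortality 0.01
  cf <- make_case_fatality_table()
  cf$fraction <- 0.3
  lt01 <- make_life_table()
  lt01$q <- 0.01
  p2 <- default_parameters(life_table = lt01, case_fatality = cf)
  M2 <- transition_matrix(person, 60, null_plan(1), p2, 1, 0.04, 0)
  expect_equal(M2["NO_CVD", "POST_CHD"], 0.028)
  expect_equal(M2["NO_CVD", "DEAD_CVD"], 0.012)
  expect_equal(M2["NO_CVD", "DEAD_OTHER"], 0.01 * (1 - 0.04))
  expect_equal(sum(M2["NO_CVD", ]), 1, tolerance = 1e-15)
})

test_that("occupancy mass is conserved and death is monotone", {
  pop <- generate_population(population_spec(n = 50, seed = 21))
  tools <- default_risk_tools()
  risks <- suppressMessages(event_risk_probabilities(pop, tools))
  sc <- scenario_spec("s", "who2019", "office", high_risk_threshold = 0.10)
  plan <- assign_treatments(pop, sc,
                            predict_combined_risk(pop, tools$who2019_office))
  tr <- simulate_cohort(pop, plan, default_parameters(), risks$p1_chd,
                        risks$p1_stroke, trace = TRUE)
  mass <- apply(tr$occupancy, c(1, 3), sum)
  expect_lt(max(abs(mass - 1), na.rm = TRUE), 1e-12)
  dead <- tr$occupancy[, 4, ] + tr$occupancy[, 5, ]
  expect_true(all(apply(dead, 1, function(x) all(diff(x) >= -1e-15))))
})

test_that("a deathless eventless person accrues exactly one QALY per cycle", {
  qp <- quiet_params(discount_rate = 0)
  person <- make_person(age = 60, baseline_utility = 1)
  out <- simulate_individual(person, null_plan(1), qp, 0, 0,
                             include_screening_cost = FALSE)
  expect_equal(out$disc_qalys, 40) # max_age 100 - age 60
  expect_equal(out$undisc_qalys, 40)
  expect_equal(out$disc_costs, 0)
  expect_equal(out$life_years, 40)
})

test_that("half-cycle-corrected discounting matches the geometric closed form", {
  for (r in c(0, 0.03, 0.06)) {
    qp <- quiet_params(discount_rate = r)
    u <- 0.85
    person <- make_person(age = 90, baseline_utility = u)
    out <- simulate_individual(person, null_plan(1), qp, 0, 0,
                               include_screening_cost = FALSE)
    # constant occupancy: the half-cycle average equals the constant flow
    closed <- sum(u * (1 + r)^(-(1:10)))
    expect_equal(out$disc_qalys, closed, tolerance = 1e-10)
  }
})

test_that("with r = 0 discounted and undiscounted totals agree exactly", {
  pop <- generate_population(population_spec(n = 30, seed = 22))
  tools <- default_risk_tools()
  risks <- suppressMessages(event_risk_probabilities(pop, tools))
  p0 <- default_parameters(discount_rate = 0)
  out <- simulate_cohort(pop, null_plan(nrow(pop)), p0, risks$p1_chd,
                         risks$p1_stroke)
  expect_identical(out$disc_qalys, out$undisc_qalys)
  expect_identical(out$disc_costs, out$undisc_costs)
})

test_that("neutral treatment changes nothing but screening/follow-up costs", {
  pop <- generate_population(population_spec(n = 100, seed = 23))
  tools <- default_risk_tools()
  risks <- suppressMessages(event_risk_probabilities(pop, tools))
  neutral <- default_parameters(
    rr_statin_nonfatal_mi = 1, rr_statin_nonfatal_stroke = 1,
    rr_statin_fatal_mi = 1, rr_statin_fatal_stroke = 1,
    rr_antihyp_nonfatal_mi = 1, rr_antihyp_nonfatal_stroke = 1,
    rr_antihyp_fatal_mi = 1, rr_antihyp_fatal_stroke = 1,
    cost_statin = 0, cost_enalapril = 0, cost_nifedipine = 0,
    cost_metformin = 0
  )
  sc <- scenario_spec("s", "who2019", "office", high_risk_threshold = 0.10)
  plan <- assign_treatments(pop, sc,
                            predict_combined_risk(pop, tools$who2019_office))
  treated <- simulate_cohort(pop, plan, neutral, risks$p1_chd, risks$p1_stroke,
                             include_screening_cost = FALSE)
  untreated <- simulate_cohort(pop, null_plan(nrow(pop)), neutral,
                               risks$p1_chd, risks$p1_stroke,
                               include_screening_cost = FALSE)
  expect_identical(treated$disc_qalys, untreated$disc_qalys)
  expect_identical(treated$events_chd_nonfatal, untreated$events_chd_nonfatal)
  # remaining cost difference is follow-up only, hence non-negative
  expect_true(all(treated$disc_costs - untreated$disc_costs >= 0))
})

test_that("weakening a treatment effect weakly reduces the QALY gain", {
  pop <- generate_population(population_spec(n = 100, seed = 24))
  tools <- default_risk_tools()
  risks <- suppressMessages(event_risk_probabilities(pop, tools))
  sc <- scenario_spec("s", "who2019", "office", high_risk_threshold = 0.10)
  plan <- assign_treatments(pop, sc,
                            predict_combined_risk(pop, tools$who2019_office))
  gain <- function(...) {
    p <- default_parameters(...)
    trt <- simulate_cohort(pop, plan, p, risks$p1_chd, risks$p1_stroke)
    unt <- simulate_cohort(pop, null_plan(nrow(pop)), p, risks$p1_chd,
                           risks$p1_stroke, include_screening_cost = FALSE)
    sum(trt$disc_qalys - unt$disc_qalys)
  }
  # fatal-event effects: averting a death always gains QALYs, so weakening
  # the effect must reduce the gain
  fatal <- vapply(c(0.82, 0.90, 1.0), function(rr)
    gain(rr_statin_fatal_mi = rr), numeric(1))
  expect_true(all(diff(fatal) <= 0))
  # non-fatal stroke: the post-stroke state is lethal and heavily disutile,
  # so preventing strokes gains QALYs and the same direction holds
  stroke <- vapply(c(0.86, 0.93, 1.0), function(rr)
    gain(rr_statin_nonfatal_stroke = rr), numeric(1))
  expect_true(all(diff(stroke) <= 0))
})

test_that("simulation is bit-identical across repeated calls", {
  pop <- generate_population(population_spec(n = 40, seed = 25))
  tools <- default_risk_tools()
  risks <- suppressMessages(event_risk_probabilities(pop, tools))
  plan <- null_plan(nrow(pop))
  a <- simulate_cohort(pop, plan, default_parameters(), risks$p1_chd,
                       risks$p1_stroke)
  b <- simulate_cohort(pop, plan, default_parameters(), risks$p1_chd,
                       risks$p1_stroke)
  expect_identical(a, b)
})

test_that("utility flows apply state decrements, age slope and pill term", {
  params <- default_parameters()
  p <- make_person(baseline_utility = 0.9)
  plan <- null_plan(1)
  expect_equal(utility_flow(p, "NO_CVD", 0, plan, params), 0.9)
  expect_equal(utility_flow(p, "POST_STROKE", 0, plan, params), 0.9 - 0.2493)
  expect_equal(utility_flow(p, "POST_CHD", 0, plan, params), 0.9 - 0.0210)
  expect_equal(utility_flow(p, "NO_CVD", 10, plan, params), 0.9 - 0.066)
  pill <- update_parameters(params, pill_disutility = 0.00384)
  medicated <- transform(plan, statin = TRUE, newly_started_any = TRUE)
  expect_equal(utility_flow(p, "NO_CVD", 0, medicated, pill), 0.9 - 0.00384)
  expect_equal(utility_flow(p, "NO_CVD", 0, plan, pill), 0.9)
  # floor: decrements cannot push utility below the configured minimum
  old <- make_person(baseline_utility = -0.9)
  expect_equal(utility_flow(old, "POST_STROKE", 20, plan, params), -1)
})

test_that("recurring cost flows add medication, follow-up and usual care", {
  params <- default_parameters(usual_care_inpatient = 0,
                               usual_care_outpatient = 0)
  statin_plan <- transform(null_plan(1), statin = TRUE,
                           newly_started_any = TRUE)
  statin_plan <- follow_up_schedule(statin_plan,
                                    scenario_spec("s", "who2019", "office"))
  # subsequent year: statin 3.98 + 1 consultation 1.96 + 1 glucose test 0.17
  expect_equal(cost_flow(make_person(), "NO_CVD", 2, statin_plan, params),
               3.98 + 1.96 + 0.17)
  # initial year has the additional follow-up
  expect_equal(cost_flow(make_person(), "NO_CVD", 1, statin_plan, params),
               3.98 + 2 * 1.96 + 0.17)
  # usual-care inflation ratios by state
  base <- default_parameters()
  uc <- function(state) cost_flow(make_person(), state, 2, null_plan(1), base)
  expect_equal(uc("NO_CVD"), 25 + 35)
  expect_equal(uc("POST_CHD"), 25 * 2.85 + 35 * 1.95)
  expect_equal(uc("POST_STROKE"), 25 * 1.09 + 35 * 1.97)
})

test_that("one full expected event books exactly one admission cost", {
  cf0 <- make_case_fatality_table()
  cf0$fraction <- 0
  qp <- quiet_params(case_fatality = cf0)
  person <- make_person(age = 99, baseline_utility = 1)
  out <- simulate_individual(person, null_plan(1), qp, p1_chd = 1,
                             p1_stroke = 0, include_screening_cost = FALSE)
  # quiet_params zeroes admission costs; re-enable the MI admission cost
  qp2 <- update_parameters(qp, cost_mi_admission = 318)
  out2 <- simulate_individual(person, null_plan(1), qp2, p1_chd = 1,
                              p1_stroke = 0, include_screening_cost = FALSE)
  expect_equal(out2$undisc_costs - out$undisc_costs, 318)
  expect_equal(out2$events_chd_nonfatal, 1)
})

test_that("screening cost covers the visit and the lab-mode cholesterol test", {
  qp <- quiet_params()
  person <- make_person(age = 99)
  office <- simulate_individual(person, null_plan(1), qp, 0, 0, mode = "office")
  lab <- simulate_individual(person, null_plan(1), qp, 0, 0, mode = "lab")
  expect_equal(office$disc_costs, 1.96 + 0.17)
  expect_equal(lab$disc_costs, 1.96 + 0.17 + 0.19)
})
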