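test_that("distribution constructors enforce their feasibility constraints", {
  expect_error(parameter_distribution("x", "uniform_pct", 1, pct = -0.1),
               "non-negative")
  expect_error(parameter_distribution("x", "lognormal_from_ci", 1,
                                      lo = 2, hi = 1), "lo < hi")
  # beta moment match infeasible when the CI-implied SD is too large
  expect_error(parameter_distribution("x", "beta_from_ci", 0.03,
                                      lo = -0.9, hi = 0.99), "infeasible")
  expect_error(parameter_distribution("x", "lognormal_disutility", -0.02,
                                      lo = -0.07, hi = 0.02, shift = 0.01),
               "shift")
})

test_that("point distributions are degenerate and draws are seed-reproducible", {
  pt <- parameter_distribution("cost_statin", "point", 3.98)
  expect_equal(draw_distribution(pt, 5), rep(3.98, 5))
  dists <- default_parameter_distributions()
  a <- draw_parameters(dists, seed = 123)
  b <- draw_parameters(dists, seed = 123)
  expect_identical(a[names(a) != "life_table"], b[names(b) != "life_table"])
  expect_error(draw_parameters(list(parameter_distribution("nope", "point", 1))),
               "unknown parameter")
})

test_that("fitted log-normal recovers the statin RR confidence interval", {
  d <- default_parameter_distributions()[["rr_statin_nonfatal_mi"]]
  sdlog <- (log(0.81) - log(0.67)) / (2 * qnorm(0.975))
  expect_equal(sdlog, 0.04841, tolerance = 1e-3)
  set.seed(31)
  x <- draw_distribution(d, 50000)
  expect_equal(unname(stats::quantile(x, 0.025)), 0.67, tolerance = 0.01)
  expect_equal(unname(stats::quantile(x, 0.975)), 0.81, tolerance = 0.01)
  expect_equal(stats::median(x), 0.74, tolerance = 0.01)
})

test_that("gamma draws recover the mean and 10% relative SD", {
  d <- default_parameter_distributions()[["cost_metformin"]]
  set.seed(32)
  x <- draw_distribution(d, 50000)
  expect_equal(mean(x), 6.27, tolerance = 0.01)
  expect_equal(stats::sd(x), 0.627, tolerance = 0.02)
  expect_true(all(x > 0))
})

test_that("negated-scale log-normal disutilities stay in their CI range", {
  dists <- default_parameter_distributions()
  set.seed(33)
  stroke <- draw_distribution(dists[["disutility_nonfatal_stroke"]], 50000)
  expect_true(all(stroke < 0))
  expect_equal(stats::median(stroke), -0.2493, tolerance = 0.01)
  # the construction anchors the median at the point value and takes sdlog
  # from the CI width; its own quantiles follow from those two facts
  z <- qnorm(0.975)
  sdlog <- (log(0.340) - log(0.158)) / (2 * z)
  expect_equal(unname(stats::quantile(stroke, 0.025)),
               -0.2493 * exp(z * sdlog), tolerance = 0.01)
  expect_equal(unname(stats::quantile(stroke, 0.975)),
               -0.2493 * exp(-z * sdlog), tolerance = 0.01)
  # the published CI is recovered up to its own log-asymmetry
  expect_equal(unname(stats::quantile(stroke, 0.025)), -0.340, tolerance = 0.1)
  expect_equal(unname(stats::quantile(stroke, 0.975)), -0.158, tolerance = 0.1)
  # the MI disutility CI crosses zero; the shifted construction respects it
  mi <- draw_distribution(dists[["disutility_nonfatal_mi"]], 50000)
  expect_equal(stats::median(mi), -0.0210, tolerance = 0.005)
  expect_true(all(mi < 0.05))
})

test_that("one-way analysis is idempotent for null overrides", {
  pop <- generate_population(population_spec(n = 400, seed = 41))
  grid <- build_scenario_grid()
  alt <- grid[["who2019_office_t10_40plus"]]
  base <- grid[["who_ish_office_t20_35plus"]]
  empty <- suppressMessages(one_way(pop, alt, base, list()))
  expect_equal(nrow(empty), 1)
  expect_equal(empty$variation, "base")

  same <- suppressMessages(
    one_way(pop, alt, base, list(null = list(discount_rate = 0.03)))
  )
  expect_identical(same$icer[1], same$icer[2])
  expect_error(one_way(pop, alt, base, list(x = list(bogus = 1))),
               "unknown parameter")
})

test_that("removing discounting raises both lifetime QALYs and costs", {
  pop <- generate_population(population_spec(n = 400, seed = 42))
  tools <- default_risk_tools()
  risks <- suppressMessages(event_risk_probabilities(pop, tools))
  sc <- scenario_spec("s", "who2019", "office", high_risk_threshold = 0.10)
  prep <- suppressMessages(prepare_scenario(pop, sc, tools))
  t03 <- evaluate_prepared(prep, pop, risks, default_parameters())
  t00 <- evaluate_prepared(prep, pop, risks,
                           default_parameters(discount_rate = 0))
  expect_gt(t00$total_qalys, t03$total_qalys)
  expect_gt(t00$total_cost, t03$total_cost)
})

test_that("PSA with point distributions reproduces the deterministic result", {
  pop <- generate_population(population_spec(n = 300, seed = 43))
  grid <- build_scenario_grid()
  scen <- grid[c("who2019_office_t20_40plus", "who2019_office_t10_40plus")]
  base <- grid[["who_ish_office_t20_35plus"]]
  pts <- list(parameter_distribution("cost_statin", "point", 3.98))
  psa <- suppressMessages(
    run_psa(pop, scen, base, distributions = pts, n_draws = 3, seed = 5)
  )
  # every draw identical
  for (id in unique(psa$draws$scenario_id)) {
    sub <- psa$draws[psa$draws$scenario_id == id, ]
    expect_equal(length(unique(sub$cost)), 1)
    expect_equal(length(unique(sub$qalys)), 1)
  }
  # degenerate CEAC: probabilities are 0 or 1 (up to tie splitting)
  expect_true(all(psa$ceac$probability %in% c(0, 0.5, 1)))
  # matches the deterministic evaluation
  tools <- default_risk_tools()
  risks <- suppressMessages(event_risk_probabilities(pop, tools))
  prep <- suppressMessages(prepare_scenario(pop, scen[[1]], tools))
  det <- evaluate_prepared(prep, pop, risks, default_parameters())
  got <- psa$draws[psa$draws$scenario_id == names(scen)[1], ]
  expect_equal(got$cost[1], det$total_cost)
  expect_equal(got$qalys[1], det$total_qalys)
})

test_that("CEAC probabilities sum to one and ties split equally", {
  pop <- generate_population(population_spec(n = 200, seed = 44))
  grid <- build_scenario_grid()
  sc <- grid[["who2019_office_t20_40plus"]]
  twin <- sc
  twin$scenario_id <- "twin"
  base <- grid[["who_ish_office_t20_35plus"]]
  psa <- suppressMessages(run_psa(
    pop, list(a = sc, twin = twin), base,
    distributions = list(parameter_distribution("cost_statin", "point", 3.98)),
    n_draws = 2, seed = 6, wtp_grid = c(0, 2000, 8000)
  ))
  sums <- tapply(psa$ceac$probability, psa$ceac$wtp, sum)
  expect_equal(as.numeric(sums), rep(1, 3))
  # identical scenarios split the optimal mass equally
  expect_true(all(psa$ceac$probability %in% c(0.5)))
  # single-draw probabilities are confined to {0, 1}
  psa1 <- suppressMessages(run_psa(
    pop, list(a = sc), base,
    distributions = list(parameter_distribution("cost_statin", "point", 3.98)),
    n_draws = 1, seed = 7, wtp_grid = c(0, 4000)
  ))
  expect_true(all(psa1$ceac$probability %in% c(0, 1)))
  expect_true(all(psa1$icer_below_threshold %in% c(0, 1)))
})

test_that("pill disutility of zero leaves the analysis unchanged", {
  pop <- generate_population(population_spec(n = 300, seed = 45))
  grid <- build_scenario_grid()
  scen <- grid["who2019_office_t10_40plus"]
  base <- grid[["who_ish_office_t20_35plus"]]
  res <- suppressMessages(
    pill_disutility_analysis(pop, scen, base, disutility = 0)
  )
  expect_equal(res$icer_change, 0)
  expect_equal(res$d_qaly_without, res$d_qaly_with)
  expect_error(pill_disutility_analysis(pop, scen, base, disutility = -1),
               "non-negative")
})

test_that("pill disutility reduces every medicated person's QALYs", {
  pop <- generate_population(population_spec(n = 300, seed = 46))
  tools <- default_risk_tools()
  risks <- suppressMessages(event_risk_probabilities(pop, tools))
  sc <- scenario_spec("s", "who2019", "office", high_risk_threshold = 0.10)
  plan <- assign_treatments(pop, sc,
                            predict_combined_risk(pop, tools$who2019_office))
  without <- simulate_cohort(pop, plan, default_parameters(), risks$p1_chd,
                             risks$p1_stroke)
  with_p <- simulate_cohort(pop, plan,
                            default_parameters(pill_disutility = 0.00384),
                            risks$p1_chd, risks$p1_stroke)
  diff_q <- without$disc_qalys - with_p$disc_qalys
  expect_true(all(diff_q >= 0))
  expect_true(all(diff_q[plan$newly_started_any] > 0))
  expect_true(all(diff_q[!plan$newly_started_any] == 0))

  # medicating more people loses more QALYs to the pill term
  plan_all <- transform(plan, statin = TRUE, newly_started_any = TRUE)
  with_all <- simulate_cohort(pop, plan_all,
                              default_parameters(pill_disutility = 0.00384),
                              risks$p1_chd, risks$p1_stroke)
  without_all <- simulate_cohort(pop, plan_all, default_parameters(),
                                 risks$p1_chd, risks$p1_stroke)
  expect_gte(sum(without_all$disc_qalys - with_all$disc_qalys), sum(diff_q))
})
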