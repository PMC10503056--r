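# Shared fixtures: single-person builder, tiny tool fixtures, and an
# independent cost-effectiveness frontier oracle.

make_person <- function(...) {
  defaults <- list(
    person_id = "P1", age = 55, sex = "male", sbp = 130, dbp = 82,
    total_cholesterol = 200, fasting_glucose = 95, random_glucose = 110,
    diabetes = FALSE, smoker = FALSE, bmi = 24, baseline_utility = 0.9,
    survey_weight = 1, prior_cvd = FALSE
  )
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  as.data.frame(defaults, stringsAsFactors = FALSE)
}

make_people <- function(n, ...) {
  rows <- do.call(rbind, replicate(n, make_person(), simplify = FALSE))
  rows$person_id <- sprintf("P%03d", seq_len(n))
  overrides <- list(...)
  for (nm in names(overrides)) rows[[nm]] <- rep_len(overrides[[nm]], n)
  rows
}

## Single-predictor equation fixture: sbp only, beta 0.02, mean 120, S0 0.95
## for both sexes.
sbp_only_equation <- function(s0 = 0.95, beta = 0.02, mean = 120) {
  block <- list(s0 = s0, predictors = data.frame(
    name = "sbp", transform = "identity", beta = beta, mean = mean,
    lo = NA_real_, hi = NA_real_, stringsAsFactors = FALSE
  ))
  risk_equation("fixture", "office", "chd",
                list(female = block, male = block))
}

## 2x2 chart fixture with known cell assignments.
tiny_chart <- function() {
  combos <- expand.grid(age_band = 1:2, sbp_band = 1:2,
                        sex = c("female", "male"), smoker = c(FALSE, TRUE),
                        diabetes = c(FALSE, TRUE), stringsAsFactors = FALSE)
  combos$category <- ifelse(combos$age_band == 2 & combos$sbp_band == 2,
                            "high", ifelse(combos$age_band == 2 | combos$sbp_band == 2,
                                           "mid", "low"))
  risk_chart("tiny", "office", age_breaks = c(40, 60, 80),
             sbp_breaks = c(100, 140, 180), cells = combos,
             category_midpoints = c(low = 0.05, mid = 0.25, high = 0.45))
}

## Parameters with all stochastic inputs switched off: zero mortality, zero
## usual-care and event costs, no age disutility. Events enter only through
## the probabilities handed to simulate_cohort().
quiet_params <- function(...) {
  lt <- make_life_table(makeham = 0, b = c(female = 0, male = 0))
  default_parameters(
    life_table = lt,
    usual_care_inpatient = 0, usual_care_outpatient = 0,
    cost_mi_admission = 0, cost_stroke_admission = 0,
    disutility_age_year = 0,
    p_death_post_chd = 0, p_death_post_stroke = 0,
    ...
  )
}

## Independent frontier oracle: gift-wrapping walk along the concave
## (cost, QALY) hull starting from the cheapest scenario. A different
## algorithm from the package's iterative dominance removal.
frontier_oracle <- function(df) {
  ord <- order(df$cost, -df$qalys, df$scenario_id)
  df <- df[ord, , drop = FALSE]
  cur <- 1L
  picked <- cur
  repeat {
    cand <- which(df$qalys > df$qalys[cur])
    cand <- cand[cand != cur]
    if (!length(cand)) break
    slopes <- (df$cost[cand] - df$cost[cur]) / (df$qalys[cand] - df$qalys[cur])
    best <- cand[slopes == min(slopes)]
    if (length(best) > 1L) {
      best <- best[order(-df$qalys[best], df$scenario_id[best])][1L]
    }
    picked <- c(picked, best)
    cur <- best
  }
  sort(df$scenario_id[picked])
}

random_cea_instance <- function(k) {
  data.frame(scenario_id = sprintf("s%02d", seq_len(k)),
             cost = stats::runif(k, 0, 100),
             qalys = stats::runif(k, 0, 50),
             stringsAsFactors = FALSE)
}
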