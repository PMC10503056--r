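# Synthetic survey cohort generator.
#
# Downstream modules consume one row per adult: demographics, blood pressure,
# lipids, glucose, flags, EQ-5D baseline utility and a survey weight. Joint
# structure is imposed with a Gaussian copula on rank correlations (NORTA) so
# configurable marginals can be coupled without claiming knowledge of the true
# joint distribution of any particular survey.

POPULATION_FIELDS <- c(
  "person_id", "age", "sex", "sbp", "dbp", "total_cholesterol",
  "fasting_glucose", "random_glucose", "diabetes", "smoker", "bmi",
  "baseline_utility", "survey_weight", "prior_cvd"
)

## Continuous fields coupled through the copula. Diastolic pressure is derived
## as sbp - pulse_pressure so that sbp > dbp holds by construction.
COPULA_FIELDS <- c(
  "age", "sbp", "pulse_pressure", "total_cholesterol",
  "fasting_glucose", "random_glucose", "bmi", "baseline_utility"
)

#' Specify a synthetic population
#'
#' Builds the configuration consumed by [generate_population()]: sample size,
#' seed, one marginal distribution per continuous field, a rank (Spearman)
#' correlation matrix coupling the continuous fields, age-gradient parameters
#' for systolic blood pressure, utility and prior-CVD prevalence, sex-specific
#' smoking prevalence, and survey-weight settings.
#'
#' Defaults are illustrative: they produce a plausible South-Asian adult risk
#' factor mix (ages 35-99, ~10% diabetes, male-dominated smoking) but are not
#' estimates of any real population.
#'
#' @param n Number of individuals.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#' @param marginals Named list of marginal specs, one per
#'   `cvdscreen:::COPULA_FIELDS` entry; each a list with `dist` in
#'   `"norm"`, `"lnorm"`, `"gamma"`, `"beta_scaled"`, `"unif"` plus its
#'   parameters and optional `min`/`max` truncation bounds.
#' @param rank_correlation Symmetric positive semi-definite Spearman
#'   correlation matrix over the copula fields (unit diagonal).
#' @param sbp_age_slope mmHg added to systolic pressure per year of age above
#'   50.
#' @param utility_age_slope Utility change per year of age above 50 (negative).
#' @param prior_cvd_intercept,prior_cvd_age_slope Logistic model for
#'   prior-CVD prevalence by age.
#' @param smoking_prevalence Named vector `c(female =, male =)` in `[0, 1]`.
#' @param p_female Probability a record is female.
#' @param p_diagnosed_diabetes Probability a person below the glucose
#'   thresholds carries a diagnosed (controlled) diabetes flag.
#' @param weight_cv Coefficient of variation of the gamma survey-weight
#'   distribution.
#' @param population_total Sum the survey weights are normalised to.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n,
                            seed = 1L,
                            marginals = default_marginals(),
                            rank_correlation = default_rank_correlation(),
                            sbp_age_slope = 0.5,
                            utility_age_slope = -0.004,
                            prior_cvd_intercept = -7.0,
                            prior_cvd_age_slope = 0.07,
                            smoking_prevalence = c(female = 0.03, male = 0.30),
                            p_female = 0.52,
                            p_diagnosed_diabetes = 0.03,
                            weight_cv = 0.5,
                            population_total = 8e6) {
  if (length(n) != 1L || is.na(n) || n < 0) {
    stop_input("`n` must be a single non-negative count")
  }
  missing_marg <- setdiff(COPULA_FIELDS, names(marginals))
  if (length(missing_marg)) {
    stop_input("marginals missing for: ", paste(missing_marg, collapse = ", "))
  }
  check_rank_correlation(rank_correlation)
  prevs <- c(smoking_prevalence, p_female, p_diagnosed_diabetes)
  if (any(prevs < 0 | prevs > 1)) {
    stop_input("prevalences must lie in [0, 1]")
  }
  structure(
    list(
      n = as.integer(n), seed = as.integer(seed), marginals = marginals,
      rank_correlation = rank_correlation, sbp_age_slope = sbp_age_slope,
      utility_age_slope = utility_age_slope,
      prior_cvd_intercept = prior_cvd_intercept,
      prior_cvd_age_slope = prior_cvd_age_slope,
      smoking_prevalence = smoking_prevalence, p_female = p_female,
      p_diagnosed_diabetes = p_diagnosed_diabetes, weight_cv = weight_cv,
      population_total = population_total
    ),
    class = "population_spec"
  )
}

check_rank_correlation <- function(R) {
  k <- length(COPULA_FIELDS)
  if (!is.matrix(R) || any(dim(R) != k)) {
    stop_input("rank_correlation must be a ", k, "x", k, " matrix over ",
               paste(COPULA_FIELDS, collapse = ", "))
  }
  if (max(abs(R - t(R))) > 1e-10) stop_input("rank_correlation must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-10) stop_input("rank_correlation must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop_input("rank_correlation is not positive semi-definite ",
               "(smallest eigenvalue ", format(min(ev)), ")")
  }
  invisible(R)
}

#' Default marginal distributions for the synthetic cohort
#'
#' Illustrative marginals for adults aged 35+; see the methods vignette for
#' the rationale behind each choice.
#' @return Named list of marginal specs.
#' @export
default_marginals <- function() {
  list(
    age = list(dist = "beta_scaled", shape1 = 1.2, shape2 = 1.8,
               min = 35, max = 100),
    sbp = list(dist = "norm", mean = 125, sd = 16, min = 80, max = 250),
    pulse_pressure = list(dist = "gamma", mean = 45, sd = 10, min = 10),
    total_cholesterol = list(dist = "norm", mean = 200, sd = 40,
                             min = 80, max = 450),
    fasting_glucose = list(dist = "lnorm", meanlog = log(95), sdlog = 0.22,
                           min = 50, max = 500),
    random_glucose = list(dist = "lnorm", meanlog = log(115), sdlog = 0.25,
                          min = 50, max = 600),
    bmi = list(dist = "norm", mean = 23.5, sd = 4, min = 13, max = 50),
    baseline_utility = list(dist = "beta_scaled", shape1 = 6, shape2 = 1.3,
                            min = 0.30, max = 1.0)
  )
}

#' Default rank-correlation matrix for the synthetic cohort
#'
#' Mild positive coupling of blood pressure, adiposity and glycaemia, a strong
#' fasting/random glucose link, and negative age-utility association.
#' @return Spearman correlation matrix over the copula fields.
#' @export
default_rank_correlation <- function() {
  k <- length(COPULA_FIELDS)
  R <- diag(k)
  dimnames(R) <- list(COPULA_FIELDS, COPULA_FIELDS)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("age", "sbp", 0.25)
  set_r("age", "total_cholesterol", 0.10)
  set_r("age", "baseline_utility", -0.25)
  set_r("sbp", "bmi", 0.20)
  set_r("total_cholesterol", "bmi", 0.15)
  set_r("fasting_glucose", "random_glucose", 0.70)
  set_r("fasting_glucose", "bmi", 0.20)
  set_r("random_glucose", "bmi", 0.15)
  set_r("sbp", "fasting_glucose", 0.10)
  R
}

## Quantile transform for one marginal spec, with optional truncation bounds
## applied by clamping (mass at the bounds, not renormalised; documented).
q_marginal <- function(u, m) {
  x <- switch(m$dist,
    norm = stats::qnorm(u, m$mean, m$sd),
    lnorm = stats::qlnorm(u, m$meanlog, m$sdlog),
    gamma = {
      shape <- if (!is.null(m$shape)) m$shape else (m$mean / m$sd)^2
      rate <- if (!is.null(m$rate)) m$rate else shape / m$mean
      stats::qgamma(u, shape = shape, rate = rate)
    },
    beta_scaled = m$min + (m$max - m$min) * stats::qbeta(u, m$shape1, m$shape2),
    unif = stats::qunif(u, m$min, m$max),
    stop_input("unknown marginal distribution: ", m$dist)
  )
  clamp(x, m$min %||% -Inf, m$max %||% Inf)
}

with_preserved_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic population
#'
#' Draws `spec$n` individuals with the joint risk-factor structure encoded in
#' the spec: continuous fields are coupled through a Gaussian copula matched
#' to the spec's Spearman correlations, systolic pressure and utility receive
#' explicit age gradients, diastolic pressure is systolic minus a positive
#' pulse pressure, smoking is sex-specific, the diabetes flag is consistent
#' with the generated glucose values, prior-CVD prevalence rises with age on a
#' logistic curve, and survey weights are positive and normalised to the
#' spec's population total.
#'
#' @param spec A [population_spec()].
#' @return A `data.frame`, one row per individual, columns as documented in
#'   [population_spec()]; deterministic given `spec` (including the seed).
#' @examples
#' pop <- generate_population(population_spec(n = 100, seed = 42))
#' summary(pop$sbp - pop$dbp) # strictly positive
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n
  if (n == 0L) {
    return(empty_population())
  }
  k <- length(COPULA_FIELDS)
  ## Spearman -> Pearson for the Gaussian copula
  R_pearson <- 2 * sin(pi * spec$rank_correlation / 6)
  diag(R_pearson) <- 1
  ev <- eigen(R_pearson, symmetric = TRUE)
  if (min(ev$values) < -1e-8) stop_input("correlation matrix not positive semi-definite")
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k) %*% t(ev$vectors)

  with_preserved_rng(spec$seed, {
    Z <- matrix(stats::rnorm(n * k), n, k) %*% L
    U <- stats::pnorm(Z)
    colnames(U) <- COPULA_FIELDS
    cols <- lapply(COPULA_FIELDS, function(f) q_marginal(U[, f], spec$marginals[[f]]))
    names(cols) <- COPULA_FIELDS

    age <- cols$age
    sbp <- clamp(cols$sbp + spec$sbp_age_slope * (age - 50), 80, 260)
    dbp <- sbp - cols$pulse_pressure
    utility <- clamp(cols$baseline_utility + spec$utility_age_slope * (age - 50),
                     -0.5, 1)

    sex <- ifelse(stats::runif(n) < spec$p_female, "female", "male")
    smoke_p <- spec$smoking_prevalence[sex]
    smoker <- stats::runif(n) < smoke_p
    prior_p <- stats::plogis(spec$prior_cvd_intercept +
                               spec$prior_cvd_age_slope * age)
    prior_cvd <- stats::runif(n) < prior_p
    diabetes <- cols$fasting_glucose >= 126 | cols$random_glucose >= 200 |
      stats::runif(n) < spec$p_diagnosed_diabetes

    shape <- 1 / spec$weight_cv^2
    w <- stats::rgamma(n, shape = shape, rate = shape)
    w <- w * spec$population_total / sum(w)

    data.frame(
      person_id = sprintf("P%06d", seq_len(n)),
      age = age, sex = sex, sbp = sbp, dbp = dbp,
      total_cholesterol = cols$total_cholesterol,
      fasting_glucose = cols$fasting_glucose,
      random_glucose = cols$random_glucose,
      diabetes = diabetes, smoker = smoker, bmi = cols$bmi,
      baseline_utility = utility, survey_weight = w, prior_cvd = prior_cvd,
      stringsAsFactors = FALSE
    )
  })
}

empty_population <- function() {
  data.frame(
    person_id = character(0), age = numeric(0), sex = character(0),
    sbp = numeric(0), dbp = numeric(0), total_cholesterol = numeric(0),
    fasting_glucose = numeric(0), random_glucose = numeric(0),
    diabetes = logical(0), smoker = logical(0), bmi = numeric(0),
    baseline_utility = numeric(0), survey_weight = numeric(0),
    prior_cvd = logical(0), stringsAsFactors = FALSE
  )
}

#' Validate a population table
#'
#' Checks the row-level invariants every downstream module assumes: positive
#' pressures with `sbp > dbp`, strictly positive glucose/cholesterol/BMI,
#' utility at most 1, non-negative weights, and a diabetes flag consistent
#' with fasting glucose at or above 126 mg/dL.
#'
#' @param pop A population `data.frame`.
#' @return `pop`, invisibly, if valid; otherwise an error naming the
#'   offending rows.
#' @export
validate_population <- function(pop) {
  missing_cols <- setdiff(POPULATION_FIELDS, names(pop))
  if (length(missing_cols)) {
    stop_input("population is missing required columns: ",
               paste(missing_cols, collapse = ", "))
  }
  problems <- character(0)
  bad <- function(mask, what) {
    idx <- which(mask)
    if (length(idx)) {
      shown <- utils::head(idx, 10L)
      problems <<- c(problems, paste0(
        what, " (rows ", paste(shown, collapse = ", "),
        if (length(idx) > 10L) ", ..." else "", ")"
      ))
    }
  }
  bad(!(pop$sbp > pop$dbp), "sbp must exceed dbp")
  bad(pop$sbp <= 0 | pop$dbp <= 0, "blood pressures must be positive")
  bad(pop$total_cholesterol <= 0, "total_cholesterol must be positive")
  bad(pop$fasting_glucose <= 0 | pop$random_glucose <= 0,
      "glucose values must be positive")
  bad(pop$bmi <= 0, "bmi must be positive")
  bad(pop$baseline_utility > 1, "baseline_utility must be at most 1")
  bad(pop$survey_weight < 0, "survey_weight must be non-negative")
  bad(pop$fasting_glucose >= 126 & !pop$diabetes,
      "diabetes flag inconsistent with fasting_glucose >= 126")
  bad(!pop$sex %in% c("female", "male"), "sex must be 'female' or 'male'")
  if (length(problems)) {
    stop_input("population validation failed:\n  - ",
               paste(problems, collapse = "\n  - "))
  }
  invisible(pop)
}

#' Write a population table to CSV
#'
#' Numeric columns are written with full (17 significant digit) precision so
#' that a write/load round trip reproduces the table exactly.
#'
#' @param pop Population `data.frame`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path) {
  out <- pop
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load and validate a population table
#'
#' Reads a delimited population file, checks the schema, ignores (with a
#' notice) any extra columns, and validates every row against the population
#' invariants.
#'
#' @param path CSV path with one header row and the columns documented in
#'   [population_spec()].
#' @return Validated population `data.frame`.
#' @export
load_population <- function(path) {
  if (!file.exists(path)) stop_input("population file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(POPULATION_FIELDS, names(raw))
  if (length(missing_cols)) {
    stop_input("population file missing required columns: ",
               paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(raw), POPULATION_FIELDS)
  if (length(extra)) {
    notify("ignoring extra population columns: ", paste(extra, collapse = ", "))
  }
  pop <- raw[POPULATION_FIELDS]
  for (f in c("diabetes", "smoker", "prior_cvd")) pop[[f]] <- as.logical(pop[[f]])
  if (anyNA(pop)) {
    stop_input("population file contains missing values (rows ",
               paste(utils::head(which(rowSums(is.na(pop)) > 0), 10L),
                     collapse = ", "), ")")
  }
  validate_population(pop)
  pop
}
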