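# Model parameter set.
#
# One flat list carries every quantity the Markov engine and costing need:
# treatment relative risks, unit costs, disutilities, post-event mortality,
# background mortality and case-fatality tables, discounting and horizons.
# Point values are a reference set for a lower-middle-income public health
# system in December-2019 USD; the background tables and usual-care base
# costs are synthetic stand-ins (see the methods vignette).

#' Default model parameters
#'
#' Returns the full parameter set with point values: statin relative risks
#' (non-fatal MI 0.74, non-fatal stroke 0.86, fatal MI 0.82, fatal stroke
#' 0.92), antihypertensive relative risks (0.86 for all four outcomes),
#' annual medication costs in USD (atorvastatin 3.98, enalapril 2.21,
#' nifedipine 0.78, metformin 6.27), test and consultation costs (glucose
#' 0.17, cholesterol 0.19, consultation 1.96), event admission costs (MI 318,
#' stroke 241), usual-care inflation ratios (inpatient CHD 2.85 / stroke
#' 1.09, outpatient CHD 1.95 / stroke 1.97, general 1.00), disutilities
#' (non-fatal MI -0.0210, non-fatal stroke -0.2493, one year of age -0.0066,
#' pill disutility 0 by default with 0.00384 as the sensitivity value),
#' post-event annual death probabilities (CHD 0.03, stroke 0.10), a 3%
#' discount rate, a 10-year treatment-effect horizon and a 100-year age cap.
#'
#' @param life_table Background mortality table; defaults to
#'   [make_life_table()].
#' @param case_fatality Case-fatality table; defaults to
#'   [make_case_fatality_table()].
#' @param ... Named overrides for any parameter.
#' @return A named list of class `parameter_set`.
#' @export
default_parameters <- function(life_table = make_life_table(),
                               case_fatality = make_case_fatality_table(),
                               ...) {
  params <- list(
    ## post-event annual mortality (replaces background mortality in the
    ## first 10 cycles; floored at background mortality)
    p_death_post_chd = 0.03,
    p_death_post_stroke = 0.10,
    ## treatment effects, relative risks over the 10-year effect horizon
    rr_statin_nonfatal_mi = 0.74,
    rr_statin_nonfatal_stroke = 0.86,
    rr_statin_fatal_mi = 0.82,
    rr_statin_fatal_stroke = 0.92,
    rr_antihyp_nonfatal_mi = 0.86,
    rr_antihyp_nonfatal_stroke = 0.86,
    rr_antihyp_fatal_mi = 0.86,
    rr_antihyp_fatal_stroke = 0.86,
    ## annual medication costs, USD
    cost_statin = 3.98,
    cost_enalapril = 2.21,
    cost_nifedipine = 0.78,
    cost_metformin = 6.27,
    ## screening / follow-up unit costs, USD
    cost_glucose_test = 0.17,
    cost_cholesterol_test = 0.19,
    cost_consultation = 1.96,
    ## event admission costs, USD
    cost_mi_admission = 318,
    cost_stroke_admission = 241,
    ## usual-care: base annual per-person costs (synthetic stand-ins) and
    ## state-specific inflation ratios
    usual_care_inpatient = 25,
    usual_care_outpatient = 35,
    ratio_general = 1.00,
    ratio_inpatient_chd = 2.85,
    ratio_inpatient_stroke = 1.09,
    ratio_outpatient_chd = 1.95,
    ratio_outpatient_stroke = 1.97,
    ## case-fatality multiplier (varied +/- 10% in PSA)
    case_fatality_scale = 1.0,
    ## utilities
    disutility_nonfatal_mi = -0.0210,
    disutility_nonfatal_stroke = -0.2493,
    disutility_age_year = -0.0066,
    pill_disutility = 0,
    utility_floor = -1,
    ## discounting and horizons
    discount_rate = 0.03,
    effect_horizon = 10,
    event_horizon = 10,
    max_age = 100,
    ## policy context
    gdp_per_capita = 4083,
    life_table = life_table,
    case_fatality = case_fatality
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(params))
  if (length(unknown)) {
    stop_input("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  params[names(overrides)] <- overrides
  validate_parameters(structure(params, class = "parameter_set"))
}

#' Validate a parameter set
#'
#' Checks domain constraints: probabilities in `[0, 1]`, relative risks
#' positive, costs non-negative, non-negative discount rate.
#' @param params A `parameter_set`.
#' @return `params`, invisibly.
#' @export
validate_parameters <- function(params) {
  probs <- c(params$p_death_post_chd, params$p_death_post_stroke)
  if (any(probs < 0 | probs > 1)) stop_input("probabilities must lie in [0, 1]")
  rrs <- unlist(params[grep("^rr_", names(params))])
  if (any(rrs <= 0)) stop_input("relative risks must be positive")
  costs <- unlist(params[grep("^cost_|^usual_care_", names(params))])
  if (any(costs < 0)) stop_input("costs must be non-negative")
  if (params$discount_rate < 0) stop_input("discount rate must be non-negative")
  invisible(params)
}

#' Modify a parameter set
#'
#' @param params A `parameter_set`.
#' @param ... Named replacements; names must already exist in `params`.
#' @return The updated, re-validated `parameter_set`.
#' @export
update_parameters <- function(params, ...) {
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(params))
  if (length(unknown)) {
    stop_input("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  params[names(overrides)] <- overrides
  validate_parameters(params)
  params
}
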