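# 10-year CVD risk scoring.
#
# Two engines: a sex-specific proportional-hazards survival equation
# (risk = 1 - S0 ^ exp(sum beta*g(x) - sum beta*g(xbar))), the functional form
# shared by the Framingham / Globorisk / WHO-2019 tool families, and a
# piecewise-constant chart lookup emulating colour-chart tools. Tool
# parameters are data, shipped as YAML files: the bundled sets are synthetic
# stand-ins with the right structure, not transcriptions of any published
# tool.

#' Construct a proportional-hazards risk equation
#'
#' @param tool_id Identifier, e.g. `"who2019_lab"`.
#' @param mode `"office"` or `"lab"`.
#' @param outcome `"chd"`, `"stroke"` or `"combined_cvd"`.
#' @param blocks Named list with elements `female` and `male`; each a list
#'   with `s0` (10-year baseline survival in (0,1)) and `predictors`, a
#'   data.frame with columns `name`, `transform` (`"identity"` or `"log"`),
#'   `beta`, `mean`, and optional `lo`/`hi` validity bounds.
#' @return An object of class `risk_equation`.
#' @export
risk_equation <- function(tool_id, mode, outcome, blocks) {
  for (sx in c("female", "male")) {
    b <- blocks[[sx]]
    if (is.null(b)) stop_input("equation block missing for sex: ", sx)
    if (!(b$s0 > 0 && b$s0 < 1)) stop_input("baseline survival must be in (0,1)")
    req <- c("name", "transform", "beta", "mean")
    if (!all(req %in% names(b$predictors))) {
      stop_input("predictor table needs columns: ", paste(req, collapse = ", "))
    }
    if (!all(b$predictors$transform %in% c("identity", "log"))) {
      stop_input("transform must be 'identity' or 'log'")
    }
  }
  structure(list(tool_id = tool_id, mode = mode, outcome = outcome,
                 blocks = blocks),
            class = "risk_equation")
}

## Numeric design column for one predictor, with validity-range clamping.
predictor_values <- function(individuals, p) {
  nm <- p[["name"]]
  if (!nm %in% names(individuals)) {
    stop_input("individual is missing predictor: ", nm)
  }
  x <- individuals[[nm]]
  if (is.logical(x)) x <- as.numeric(x)
  if (!is.numeric(x)) stop_input("predictor must be numeric: ", nm)
  lo <- p[["lo"]]
  hi <- p[["hi"]]
  if (!is.null(lo) && !all(is.na(c(lo, hi)))) {
    n_clamped <- sum(x < lo | x > hi)
    if (n_clamped > 0) {
      notify("clamped ", n_clamped, " value(s) of '", nm,
             "' to validity range [", lo, ", ", hi, "]")
      x <- clamp(x, lo, hi)
    }
  }
  if (identical(p[["transform"]], "log")) {
    if (any(x <= 0)) stop_input("log transform needs positive values: ", nm)
    x <- log(x)
  }
  x
}

#' Predict 10-year risk with a proportional-hazards equation
#'
#' Computes `1 - S0 ^ exp(lp - lp_ref)` per individual, where `lp` is the
#' linear predictor at the individual's (transformed, range-clamped) values
#' and `lp_ref` the linear predictor at the tool's reference means, using the
#' sex-specific block matching each row.
#'
#' @param individuals Population `data.frame` (or a single-row slice).
#' @param model A [risk_equation()].
#' @return Numeric vector of 10-year event probabilities in `[0, 1]`.
#' @export
predict_10yr_risk_equation <- function(individuals, model) {
  stopifnot(inherits(model, "risk_equation"))
  n <- nrow(individuals)
  out <- numeric(n)
  for (sx in c("female", "male")) {
    idx <- which(individuals$sex == sx)
    if (!length(idx)) next
    blk <- model$blocks[[sx]]
    preds <- blk$predictors
    sub <- individuals[idx, , drop = FALSE]
    lp <- 0
    lp_ref <- 0
    for (i in seq_len(nrow(preds))) {
      p <- as.list(preds[i, , drop = FALSE])
      xv <- predictor_values(sub, p)
      mref <- p[["mean"]]
      if (identical(p[["transform"]], "log")) mref <- log(mref)
      lp <- lp + p[["beta"]] * xv
      lp_ref <- lp_ref + p[["beta"]] * mref
    }
    out[idx] <- 1 - blk$s0^exp(lp - lp_ref)
  }
  clamp(out, 0, 1)
}

#' Construct a risk chart
#'
#' A chart assigns every combination of age band, systolic-pressure band,
#' sex, smoking and diabetes a risk category, and each category a point
#' 10-year probability (its midpoint). Bands are half-open `[lower, upper)`;
#' values outside the outermost bands are clamped to the nearest band with a
#' notice.
#'
#' @param tool_id,mode Identifiers as in [risk_equation()].
#' @param age_breaks,sbp_breaks Ordered numeric bin edges (length k+1 for k
#'   bands).
#' @param cells `data.frame` with columns `age_band`, `sbp_band` (1-based
#'   band indices), `sex`, `smoker`, `diabetes`, `category`; must cover every
#'   combination exactly once.
#' @param category_midpoints Named numeric vector, strictly increasing in
#'   category order, values in `[0, 1]`.
#' @return An object of class `risk_chart` (outcome `"combined_cvd"`).
#' @export
risk_chart <- function(tool_id, mode, age_breaks, sbp_breaks, cells,
                       category_midpoints) {
  if (is.unsorted(age_breaks, strictly = TRUE) ||
      is.unsorted(sbp_breaks, strictly = TRUE)) {
    stop_input("chart bin edges must be strictly increasing")
  }
  if (is.unsorted(category_midpoints, strictly = TRUE)) {
    stop_input("category midpoints must be strictly increasing")
  }
  n_age <- length(age_breaks) - 1L
  n_sbp <- length(sbp_breaks) - 1L
  want <- n_age * n_sbp * 2L * 2L * 2L
  key <- with(cells, paste(age_band, sbp_band, sex, smoker, diabetes))
  if (anyDuplicated(key)) stop_input("chart cells contain duplicate combinations")
  if (nrow(cells) != want) {
    stop_input("chart must define exactly ", want, " cells, got ", nrow(cells))
  }
  if (!all(cells$category %in% names(category_midpoints))) {
    stop_input("cell categories must appear in category_midpoints")
  }
  lut <- array(NA_character_, dim = c(n_age, n_sbp, 2L, 2L, 2L))
  sex_i <- match(cells$sex, c("female", "male"))
  lut[cbind(cells$age_band, cells$sbp_band, sex_i,
            cells$smoker + 1L, cells$diabetes + 1L)] <- cells$category
  structure(list(tool_id = tool_id, mode = mode, outcome = "combined_cvd",
                 age_breaks = age_breaks, sbp_breaks = sbp_breaks,
                 cells = cells, lut = lut,
                 category_midpoints = category_midpoints),
            class = "risk_chart")
}

## Half-open [lower, upper) band index with clamping to the outer bands.
band_index <- function(x, breaks, what) {
  i <- findInterval(x, breaks, left.open = FALSE, rightmost.closed = FALSE)
  n_out <- sum(i < 1L | i > length(breaks) - 1L)
  if (n_out > 0) {
    notify("clamped ", n_out, " ", what, " value(s) to the outermost chart band")
  }
  clamp(i, 1L, length(breaks) - 1L)
}

#' Predict 10-year risk from a chart
#'
#' Deterministic table lookup: each individual falls in exactly one cell and
#' receives that cell's category midpoint.
#'
#' @inheritParams predict_10yr_risk_equation
#' @param chart A [risk_chart()].
#' @return Numeric vector of 10-year combined-CVD probabilities.
#' @export
predict_10yr_risk_chart <- function(individuals, chart) {
  stopifnot(inherits(chart, "risk_chart"))
  ai <- band_index(individuals$age, chart$age_breaks, "age")
  si <- band_index(individuals$sbp, chart$sbp_breaks, "sbp")
  sex_i <- match(individuals$sex, c("female", "male"))
  cat <- chart$lut[cbind(ai, si, sex_i,
                         as.integer(individuals$smoker) + 1L,
                         as.integer(individuals$diabetes) + 1L)]
  unname(chart$category_midpoints[cat])
}

#' Convert a 10-year probability to an annual probability
#'
#' Constant-hazard conversion `p1 = 1 - (1 - p10)^(1/h)`, the inverse of
#' compounding an annual probability over `h` years.
#'
#' @param p10 Probabilities in `[0, 1]` (vectorised).
#' @param horizon_years Conversion horizon, default 10.
#' @return Annual probabilities; satisfies
#'   `1 - (1 - annualize_probability(p))^horizon_years == p` to numerical
#'   precision.
#' @export
annualize_probability <- function(p10, horizon_years = 10) {
  if (any(is.na(p10)) || any(p10 < 0 | p10 > 1)) {
    stop_input("p10 must lie in [0, 1]")
  }
  1 - (1 - p10)^(1 / horizon_years)
}

#' Combine independent CHD and stroke probabilities
#'
#' `1 - (1 - p_chd) * (1 - p_stroke)`: the probability of at least one event
#' type, used to classify total CVD risk for tools reporting the two
#' outcomes separately.
#' @param p_chd,p_stroke Probabilities in `[0, 1]`.
#' @return Combined probabilities.
#' @export
combine_risks <- function(p_chd, p_stroke) {
  1 - (1 - p_chd) * (1 - p_stroke)
}

#' Predict the combined 10-year CVD risk for any tool
#'
#' Dispatches on tool type: chart tools return their cell midpoint directly;
#' equation tool sets score CHD and stroke separately and combine them with
#' [combine_risks()].
#'
#' @inheritParams predict_10yr_risk_equation
#' @param tool A tool object from [load_risk_tool()] or
#'   [default_risk_tools()].
#' @return Numeric vector of combined 10-year CVD probabilities.
#' @export
predict_combined_risk <- function(individuals, tool) {
  if (inherits(tool, "risk_chart")) {
    return(predict_10yr_risk_chart(individuals, tool))
  }
  if (!is.list(tool) || is.null(tool$chd) || is.null(tool$stroke)) {
    stop_input("tool must be a risk_chart or a list with chd and stroke equations")
  }
  combine_risks(predict_10yr_risk_equation(individuals, tool$chd),
                predict_10yr_risk_equation(individuals, tool$stroke))
}
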