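# Background mortality and case fatality.
#
# The engine needs (a) an annual probability of death without a CVD event by
# sex and age, and (b) the fraction of incident CHD / stroke events that are
# fatal in the event year, by sex and 5-year age group. Both are supplied as
# tables; the bundled constructors generate synthetic tables (Gompertz-
# Makeham mortality, age-increasing case fatality) standing in for national
# life tables and burden-of-disease estimates, which are inputs, not outputs,
# of this package.

#' Synthetic life table
#'
#' Annual probability of death by sex and 5-year age band from a
#' Gompertz-Makeham hazard `h(a) = makeham + b * exp(c * a)`, evaluated at the
#' band midpoint. Bands are half-open `[age_lo, age_hi)` and cover ages 0-105
#' so every model age up to the 100-year cap is covered.
#'
#' @param makeham Age-independent hazard component.
#' @param b,c Gompertz scale (sex-specific, named vector `female`/`male`) and
#'   shape.
#' @return `data.frame` with columns `sex`, `age_lo`, `age_hi`, `q`.
#' @export
make_life_table <- function(makeham = 5e-4,
                            b = c(female = 1.6e-5, male = 3.0e-5),
                            c = 0.092) {
  age_lo <- seq(0, 100, by = 5)
  rows <- do.call(rbind, lapply(c("female", "male"), function(sx) {
    mid <- age_lo + 2.5
    h <- makeham + b[[sx]] * exp(c * mid)
    data.frame(sex = sx, age_lo = age_lo, age_hi = age_lo + 5,
               q = 1 - exp(-h), stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

#' Synthetic case-fatality table
#'
#' Fraction of incident events fatal in the event year by condition, sex and
#' 5-year age band (half-open), increasing linearly with age and clamped to
#' `[0.05, 0.95]`.
#'
#' @param base Named list of baseline fractions at age 50 per condition and
#'   sex.
#' @param slope Increase in the fatal fraction per year of age.
#' @return `data.frame` with columns `condition`, `sex`, `age_lo`, `age_hi`,
#'   `fraction`.
#' @export
make_case_fatality_table <- function(base = list(
                                       chd = c(female = 0.30, male = 0.35),
                                       stroke = c(female = 0.22, male = 0.25)
                                     ),
                                     slope = 0.005) {
  age_lo <- seq(30, 100, by = 5)
  rows <- do.call(rbind, lapply(names(base), function(cond) {
    do.call(rbind, lapply(c("female", "male"), function(sx) {
      mid <- age_lo + 2.5
      frac <- clamp(base[[cond]][[sx]] + slope * (mid - 50), 0.05, 0.95)
      data.frame(condition = cond, sex = sx, age_lo = age_lo,
                 age_hi = age_lo + 5, fraction = frac,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  rows
}

## Banded lookup shared by both tables: returns the value column for each
## (key, age) pair; errors (no extrapolation) when an age is uncovered.
banded_lookup <- function(table, keys, ages, value_col, label) {
  out <- rep(NA_real_, length(ages))
  for (key in unique(keys)) {
    sub <- table[table$.key == key, , drop = FALSE]
    idx <- which(keys == key)
    if (!nrow(sub)) stop_input(label, " has no rows for ", key)
    band <- findInterval(ages[idx], sub$age_lo, left.open = FALSE)
    bad <- band < 1L | ages[idx] >= max(sub$age_hi)
    if (any(bad)) {
      stop_input(label, " does not cover age(s) ",
                 paste(utils::head(ages[idx][bad], 5L), collapse = ", "),
                 " for ", key)
    }
    out[idx] <- sub[[value_col]][band]
  }
  out
}

#' Look up annual background mortality
#'
#' @param life_table Table from [make_life_table()] or a user-supplied table
#'   with the same columns.
#' @param age,sex Vectors (recycled to common length).
#' @return Annual probability of death without a CVD event.
#' @export
life_table_q <- function(life_table, age, sex) {
  n <- max(length(age), length(sex))
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  lt <- life_table
  lt$.key <- lt$sex
  banded_lookup(lt, sex, age, "q", "life table")
}

#' Look up the fatal fraction of incident events
#'
#' @param table Table from [make_case_fatality_table()].
#' @param condition `"chd"` or `"stroke"` (scalar or vector).
#' @param age,sex Vectors.
#' @return Fatal fraction in `[0, 1]`.
#' @export
case_fatality_fraction <- function(table, condition, age, sex) {
  n <- max(length(age), length(sex), length(condition))
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  condition <- rep_len(condition, n)
  tb <- table
  tb$.key <- paste(tb$condition, tb$sex)
  banded_lookup(tb, paste(condition, sex), age, "fraction", "case-fatality table")
}

#' Split an annual event probability into fatal and non-fatal parts
#'
#' `p_fatal = p_event * fraction`, `p_nonfatal = p_event - p_fatal`, so the
#' two parts always sum to `p_event` exactly.
#'
#' @param p_event Annual event probability (vectorised).
#' @param condition,age,sex Keys into the case-fatality table.
#' @param table Case-fatality table.
#' @return List with components `p_fatal` and `p_nonfatal`.
#' @export
split_fatal_nonfatal <- function(p_event, condition, age, sex, table) {
  frac <- case_fatality_fraction(table, condition, age, sex)
  p_fatal <- p_event * frac
  list(p_fatal = p_fatal, p_nonfatal = p_event - p_fatal)
}
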