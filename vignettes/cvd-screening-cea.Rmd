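---
title: "Methods: lifetime cost-effectiveness of CVD risk screening designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifetime cost-effectiveness of CVD risk screening designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdscreen)
```

# The decision problem

A public screening program for cardiovascular disease (CVD) risk is defined
by a handful of design choices: the age group screened, the risk prediction
tool (office-based, using only measurements available at the clinic, or
lab-based, adding a cholesterol test), the 10-year risk threshold that
classifies a person as "high CVD risk", and two optional treatment
extensions — prescribing antihypertensives at a lowered blood-pressure
threshold (130/80 instead of 140/90) to diabetics and high-risk people, and
prescribing statins to all diabetics regardless of risk. `cvdscreen`
quantifies, for every combination of these choices, the lifetime costs and
quality-adjusted life years (QALYs) of screening one year's cohort through a
network of primary-care clinics, and ranks the designs by incremental
cost-effectiveness.

The default grid couples 8 tools × 2 age rules × 2 thresholds × 2 × 2 policy
flags, plus the previous national protocol (30% threshold, ages 40–65) as a
distinguished extra design: 129 scenarios, with the current protocol
(office chart tool, 20% threshold, 35+) as the comparator. Program
throughput defaults to `hlc_capacity()` = 20 patients/week × 1,000 clinics ×
48 weeks × 70% utilisation = 672,000 screened persons per year.

# Risk scoring

Two engines cover the published tool families:

* **Equation tools** use the sex-specific proportional-hazards survival form
  $\text{risk} = 1 - S_0^{\exp(\sum_j \beta_j g_j(x_j) - \sum_j \beta_j
  g_j(\bar x_j))}$ with $S_0$ the 10-year baseline survival, $g_j$ either the
  identity or the natural log, and $\bar x_j$ the predictor reference means.
  Predictors outside a tool's declared validity range are clamped to it with
  a logged notice — survey data contain extremes and silently extrapolating a
  hazard model beyond its support is worse than saturating it.
* **Chart tools** are piecewise-constant lookups over age and systolic
  pressure bands crossed with sex, smoking and diabetes; each cell carries a
  risk category whose midpoint is used as the point probability. Bands are
  half-open `[lower, upper)` with the lower edge inclusive — a convention
  that must simply be fixed for determinism — and values beyond the outer
  bands clamp to the nearest band with a notice.

Tool parameters are *data*, shipped as YAML files under
`inst/extdata/risk_tools/` and validated on load. The bundled files are
synthetic stand-ins (each is flagged `synthetic: true`): they have the
structure, predictor sets and plausible gradients of the published
office/lab families, but none of their coefficients is a transcription of a
published tool. Anyone with access to calibrated coefficients can drop in
replacement files.

Classification uses each scenario's own tool; tools that score CHD and
stroke separately are combined as $p = 1-(1-p_{\text{CHD}})(1-p_{\text{stroke}})$.
Event *simulation*, by contrast, always uses one designated lab-mode
equation tool as ground truth, mirroring the separation between how a
program classifies people and what actually happens to them. Ten-year
probabilities convert to annual ones by the constant-hazard relation
$p_1 = 1-(1-p_{10})^{1/10}$, whose inverse is exact to machine precision.

# Treatment rules and follow-up

Within a scenario, a screened person is treated according to guideline
logic: antihypertensives at blood pressure ≥ 140/90 mmHg (an OR over the
systolic and diastolic readings, the standard clinical convention for
slash-notation thresholds), extended to ≥ 130/80 for diabetics and
high-risk people when the lowered-threshold flag is on; hypoglycaemics at
fasting glucose ≥ 126 mg/dL or random glucose ≥ 200 mg/dL, or for anyone
already carrying a diabetes diagnosis (the diabetic-specific policies are
interpreted as targeting *all* diabetics, including diagnosed-but-controlled
ones); statins for high CVD risk, for total cholesterol ≥ 300 mg/dL in lab
scenarios, or for all diabetics under that flag. Medication, once started,
continues for life; its risk-reducing effect is limited to the first 10
years (a conservative effect horizon), which also bounds the event window of
the state model.

Follow-up is two-tier: high-risk people get two visits and two glucose tests
per year (plus a cholesterol test per visit in lab scenarios); medicated
non-high-risk people get one visit and one glucose test per year with one
extra visit in the first year. Whether lab-scenario cholesterol findings
alone should trigger the high-risk follow-up frequency is not specified
anywhere we could find; the package keeps such people on the lower tier,
which matches the two-tier rule's letter.

# The lifetime Markov model

Each screened individual is propagated as an expected-value occupancy
distribution over five states — no CVD, post-CHD, post-stroke, CVD death,
non-CVD death — in 1-year cycles from their age at screening to at most age
100. This cohort-style propagation per individual is deliberate: the model
is a Markov chain with known transition probabilities, so first-order Monte
Carlo noise would only obscure results; parameter uncertainty is carried by
the probabilistic sensitivity analysis instead.

Within the first 10 cycles, a person in the no-CVD state faces annual CHD
and stroke event probabilities (ground-truth tool, annualised), each split
into fatal and non-fatal parts by a sex- and 5-year-age-band case-fatality
fraction. Competing risks within a cycle are resolved by applying background
mortality to the event-free remainder, $q \cdot (1 - p_{\text{events}})$,
which avoids double-counting death. Non-fatal events move the person to the
corresponding post-event state; fatal events and post-event deaths go to CVD
death. Post-event states use fixed annual death probabilities (0.03 post-CHD,
0.10 post-stroke) *instead of* background mortality during the event window
— these rates already embed the elevated mortality from subsequent events —
floored at the life-table value so an elderly person is never modelled as
safer after an event than the life table allows. After cycle 10, every alive
state faces background mortality only, and no further events occur.
Recurrent events are intentionally out of scope, as is any morbidity benefit
of diabetes treatment beyond CVD.

One structural caveat follows directly from the no-repeat-events design and
is worth stating because it occasionally surprises: the post-CHD state
shelters its occupants from further event risk, so for an elderly high-risk
person whose background-plus-fatal-event hazard in the no-CVD state exceeds
the post-CHD death rate, a *non-fatal MI can be QALY-favourable in
expectation*. A consequence is that the QALY gain from treatment is not
globally monotone in the non-fatal-MI relative risk; it is monotone in the
fatal-event relative risks and in the stroke relative risks (the post-stroke
state is both lethal and heavily disutile), and the test suite asserts
exactly those directions.

## Utilities and costs

Annual utility is the person's baseline EQ-5D index plus an age slope
(−0.0066 per year since screening), a state decrement (−0.0210 post-CHD,
−0.2493 post-stroke), and, when enabled, a pill disutility (0.00384)
for anyone newly started on any medication; the sum is floored at −1 so that
additive decrements cannot diverge at extreme ages. Annual costs sum
medication (statin 3.98, antihypertensive regimen 2.21 + 0.78 — both listed
drugs, jointly, a choice the source leaves open — metformin 6.27 USD/year),
follow-up consultations (1.96) and tests (glucose 0.17, cholesterol 0.19),
usual care (base inpatient/outpatient per-person costs scaled by
state-specific inflation ratios: 2.85/1.95 inpatient/outpatient post-CHD,
1.09/1.97 post-stroke, 1.00 otherwise), and event admissions (MI 318, stroke
241) charged to the incident event mass in its cycle. The screening visit
itself (consultation + glucose test + cholesterol test in lab mode) is a
one-off year-0 cost. All monetary values are December-2019 USD.

The base annual usual-care costs (default 25 inpatient + 35 outpatient
USD/person-year) are illustrative placeholders of the right order for a
lower-middle-income public system; they are ordinary parameters and should
be replaced with local estimates for any real application.

## Half-cycle correction and discounting

Recurring flows (utility, medication, follow-up, usual care) are valued at
the mean of start- and end-of-cycle occupancy — the standard half-cycle
correction — and discounted at $1/(1+r)^t$ with $r = 3\%$/year by default.
One-off flows (the screening visit, event admissions) are charged at their
cycle without half-cycle correction. With constant occupancy the discounted
QALY total reduces to the geometric sum $\sum_t u\,(1+r)^{-t}$, which the
tests verify to $10^{-10}$ at $r \in \{0, 0.03, 0.06\}$; occupancy mass is
conserved to $10^{-12}$ every cycle.

# Program-level cost-effectiveness

Program totals are the survey-weighted mean *net* outcome per screened
person times the annual screening capacity, where net means treated minus
the same cohort's no-program counterfactual (same persons, no screening
visit, no treatment, no follow-up). Netting is what makes designs with
different eligible age groups comparable at all: gross lifetime QALY totals
of a 35+ cohort and a 40–65 cohort differ by hundreds of thousands of QALYs
for purely demographic reasons, swamping any program effect, whereas net
totals isolate what the program itself buys. The untreated arm depends only
on the eligibility rule, so it is computed once per age rule and shared
across scenarios.

Increments are taken against the base-case scenario. Dominance follows the
standard two-stage procedure: strong dominance removes any scenario that
another matches or beats on both cost and QALYs (exact ties keep the
lexicographically smaller id, for determinism); extended dominance then
iteratively removes scenarios until pairwise ICERs increase strictly along
the cost-ordered survivors. The surviving set is the cost-effectiveness
frontier. The test suite checks this algorithm against an independent
gift-wrapping hull construction on hundreds of random instances. ICERs are
kept at full precision internally and rounded only for display; cheaper,
less effective scenarios are reported as savings per QALY forgone and are
excluded from threshold classification, which otherwise assigns each ICER
the smallest of 0.25×, 0.5× and 1× GDP per capita (default 4,083 USD) that
covers it, boundaries inclusive.

Age-subgroup analysis repeats the within-band netting and scaling for
half-open 5-year bands of age at screening; empty bands are omitted with a
notice.

# Sensitivity analysis

**One-way (deterministic).** `one_way()` re-runs the scenario-versus-base
comparison once per named override set; `default_one_way_variations()`
bundles the standard ones: a stronger antihypertensive effect on non-fatal
stroke, discounting at 0% and 6%, deepening the MI disutility to the stroke
value, usual care at 80%/120%, and usual-care inflation ratios forced to 1
and 3.

**Pill disutility.** A separate analysis subtracts 0.00384 from the annual
utility of everyone newly medicated and reports the per-scenario ICER
shift. The QALY loss is linear in medicated person-years, so designs that
medicate more people lose more.

**Probabilistic.** `run_psa()` draws full parameter sets (1,000 draws by
default) and applies each draw to every scenario and the base — common
random parameters within a draw — then computes cost-effectiveness
acceptability curves by net-monetary-benefit argmax over a
willingness-to-pay grid (default 0 to 2× GDP per capita in 41 steps,
spanning the landmark thresholds), splitting ties equally, and the
per-scenario probability that the ICER versus base is at or below a stated
threshold, counting cost-saving draws as below.

Distributions are reconstructed from published point values and 95% CIs:
uniform ±x%, gamma from mean and 10% relative SD, beta matched to mean and
CI-implied SD (infeasible matches are a configuration error), and
log-normal with `meanlog = log(point)` and `sdlog = (log hi − log lo)/(2
× 1.959964)`. The log-normal construction anchors the *median* at the point
value, so a CI that is asymmetric on the log scale is recovered only
approximately — the statin relative-risk CIs are log-symmetric and recover
to about half a percent. Disutilities declared log-normal are sampled on the
negated scale; the non-fatal-MI CI spans zero, so its draws use a fixed
location shift of 0.05 (sampling $y = 0.05 - x$ log-normally), a
construction chosen for simplicity and recorded here because the source
specification leaves the transform open.

# The synthetic population

`generate_population()` stands in for the individual-level survey the
original analysis consumed. It couples configurable marginals through a
Gaussian copula matched to a Spearman rank-correlation matrix (the NORTA
construction, with the $2\sin(\pi\rho_s/6)$ rank-to-Pearson conversion),
then applies explicit age gradients: systolic pressure +0.5 mmHg/year above
age 50, utility −0.004/year, and a logistic age curve for prior-CVD
prevalence. Diastolic pressure is systolic minus a positive pulse pressure,
so `sbp > dbp` holds by construction rather than by rejection. Smoking is
sex-specific (30% male, 3% female by default), the diabetes flag is set for
fasting glucose ≥ 126 mg/dL or random glucose ≥ 200 mg/dL plus a small
diagnosed-but-controlled fraction, and survey weights are gamma-distributed
and normalised to a configurable population total. Ages default to [35, 100)
because the model screens from 35 and caps at 100.

What the generator emulates: the *joint structure* downstream code assumes —
age-correlated blood pressure and utility, glucose consistency, rising
prior-CVD prevalence, weight dispersion. What it does not emulate: any real
country's marginals, cluster sampling design, or missingness (records are
complete by construction). Passing tests therefore demonstrate correctness
of the machinery on realistic structure, not calibration to any population;
every default is illustrative and should be re-specified for applied work.

# Numerical and design choices

* Seeds: every stochastic entry point takes an explicit seed; the pipeline
  expands one root seed into per-stage streams. The generator saves and
  restores the caller's RNG state.
* Integer ages: age-dependent lookups use the individual's integer age in
  the current cycle; life-table and case-fatality bands are half-open
  5-year bands, and uncovered ages are an error rather than an
  extrapolation.
* Event probabilities after treatment effects are clamped to [0, 1]; the
  all-cause event total is clamped before the competing-risk split.
* The synthetic life table is Gompertz–Makeham
  ($h = a + b e^{c\,\text{age}}$, sex-specific $b$); the synthetic
  case-fatality fractions rise linearly with age, clamped to [0.05, 0.95].
  Both are replaceable data inputs.
* Problem sizes: the bundled acceptance script uses a 4,000-person cohort
  for the 129-scenario grid and an 800-person cohort with 1,000 draws for
  the PSA; the test suite uses cohorts of 50–2,000. These sizes give stable
  qualitative results for the synthetic calibration while keeping a full
  run in minutes on one core.

# Known limitations

Beyond the deliberate scope exclusions (no repeat events, no diabetes
microvascular outcomes, no adherence or real-world uptake, public-payer
perspective only), the main caveats are: the bundled tools, tables and
usual-care base costs are synthetic stand-ins, so absolute ICERs produced
with the defaults are demonstrations, not estimates; the post-event-state
sheltering artifact described above; and the log-normal CI reconstruction's
median-anchoring, which slightly reshapes strongly asymmetric published
intervals.
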