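# cvdscreen

Cost-effectiveness modelling of cardiovascular disease (CVD) risk screening
program designs for low-resource health systems.

National screening programs for CVD risk must decide **who** to screen (age
groups), **how** to assess risk (office- or laboratory-based prediction
tools), and **what thresholds** trigger treatment (the 10-year risk cut-off
for statins, lowered blood-pressure thresholds for diabetics and high-risk
people, statins for all diabetics). Each choice changes both the health
impact and the cost of the program. `cvdscreen` implements the full
evaluation pipeline for such design questions:

1. **Synthetic population** — seedable cohorts with realistic joint
   risk-factor structure (Gaussian copula over configurable marginals,
   age gradients for blood pressure, utility and prior CVD, sex-specific
   smoking, glucose-consistent diabetes flags, survey weights).
2. **Risk scoring** — sex-specific proportional-hazards survival equations
   `risk = 1 − S₀^exp(Σβg(x) − Σβg(x̄))` and piecewise-constant chart
   lookups, with 10-year → 1-year probability conversion
   `p₁ = 1 − (1 − p₁₀)^(1/10)`.
3. **Screening policy** — eligibility, high-risk classification, guideline
   treatment rules (BP ≥ 140/90; fasting glucose ≥ 126 / random ≥ 200
   mg/dL; total cholesterol ≥ 300 mg/dL in lab scenarios), two-tier
   follow-up schedules, and the full scenario grid (8 tools × 2 age rules ×
   2 risk thresholds × 2 × 2 policy flags + the previous national protocol
   = 129 designs).
4. **Lifetime Markov model** — five states (no CVD, post-CHD, post-stroke,
   CVD death, non-CVD death), 1-year cycles to age 100, events in the first
   10 cycles split fatal/non-fatal by sex- and age-specific case fatality,
   treatment relative risks over a 10-year effect horizon, half-cycle
   corrected QALY and cost flows discounted at 3%/year.
5. **CEA** — program totals net of the same cohort's no-program
   counterfactual, scaled to a 672,000-person screening year; increments
   vs the base case; strong and extended dominance; the cost-effectiveness
   frontier; GDP-per-capita threshold bands; 5-year age-subgroup ICERs.
6. **Sensitivity analysis** — one-way deterministic variations (tornado),
   pill-disutility analysis, and probabilistic sensitivity analysis with
   cost-effectiveness acceptability curves (net-monetary-benefit argmax
   over 1,000 parameter draws from CI-derived distributions).

The bundled risk-tool coefficient files, life table and case-fatality
tables are clearly-labelled synthetic stand-ins with the structure (not the
values) of their published counterparts; all of them are data inputs that
can be replaced with calibrated files.

## Worked example

```r
library(cvdscreen)

pop  <- generate_population(population_spec(n = 2000, seed = 42))
grid <- build_scenario_grid(tools = c("who_ish:office", "who2019:office"),
                            age_rules = c("35plus", "40plus"),
                            thresholds = c(0.20, 0.10))
res  <- run_pipeline(population = pop, scenarios = grid)

tab <- as.data.frame(res$cea)
out <- data.frame(scenario = tab$scenario_id,
                  cost_musd = round(tab$cost / 1e6, 2),
                  d_qaly = round(tab$d_qaly),
                  icer = round(tab$icer),
                  dominance = tab$dominance)
print(head(out[order(out$cost_musd), ], 14), row.names = FALSE)
```

```
                         scenario cost_musd d_qaly   icer        dominance
        who2019_office_t20_35plus     35.46  -6649   1426         frontier
        who_ish_office_t30_40to65     36.09 -20746    427 dominated_strong
        who2019_office_t20_40plus     36.29  -4292   2017         frontier
    who2019_office_t20_35plus_lbp     36.55  -5518   1521 dominated_strong
    who2019_office_t20_40plus_lbp     37.27  -3074   2495         frontier
     who2019_office_t20_35plus_sd     40.57  -4095   1068 dominated_strong
     who2019_office_t20_40plus_sd     40.93  -1614   2486   dominated_weak
        who2019_office_t10_35plus     41.62  -1676   1979 dominated_strong
 who2019_office_t20_35plus_sd_lbp     41.67  -3038   1075 dominated_strong
 who2019_office_t20_40plus_sd_lbp     41.93   -473   6370   dominated_weak
        who2019_office_t10_40plus     43.13   1227  -1477   dominated_weak
    who2019_office_t10_35plus_lbp     43.16     66 -27111 dominated_strong
    who2019_office_t10_40plus_lbp     44.61   3123   -107         frontier
        who_ish_office_t20_35plus     44.94      0     NA dominated_strong
```

and the frontier with the ICER of each step along it:

```
                         scenario cost_musd step_icer
        who2019_office_t20_35plus     35.46        NA
        who2019_office_t20_40plus     36.29       351
    who2019_office_t20_40plus_lbp     37.27       810
    who2019_office_t10_40plus_lbp     44.61      1183
    who_ish_office_t20_40plus_lbp     48.38      1960
 who_ish_office_t20_40plus_sd_lbp     51.85      2988
    who_ish_office_t10_40plus_lbp     78.96      3774
 who_ish_office_t10_40plus_sd_lbp     80.30      5550
```

Reading it: `cost_musd` is the lifetime cost of screening one 672,000
person cohort, **net of what the same people would have cost with no
program**; `d_qaly` and `icer` are increments versus the base case (the
current protocol: WHO-ISH office tool, 20% threshold, ages 35+, zero by
construction). Scenarios above the base in the table save money; those
with negative `d_qaly` also lose QALYs (the ratio is then savings per QALY
forgone), while a negative `icer` with positive `d_qaly` marks the
cost-saving-and-more-effective quadrant. `dominance` labels scenarios
excluded from the frontier because another design gives more QALYs at
lower cost (`dominated_strong`) or at a lower ICER (`dominated_weak`) —
note the base case itself can be dominated. `render_reports(res, dir)`
writes the CSV tables, the frontier scatter, tornado and CEAC figures plus
a JSON manifest.

Note the numbers above come from the bundled *synthetic* tools and
population defaults — they demonstrate the mechanics, not Sri Lankan (or
any other) policy estimates.

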