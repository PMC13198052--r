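# prehabcea

Trial-based economic evaluation of multimodal prehabilitation for elderly
(pre-)frail patients before elective surgery, from a societal perspective.

Prehabilitation — a short, multimodal preoperative programme of supervised
exercise, nutrition counselling and cognitive support, preceded by frailty
screening and a shared decision-making conference — aims to build the
physiological reserve of older surgical patients. Whether it is worth paying
for is a health-economic question: the intervention itself is costly, and its
benefits arrive as quality of life, avoided care dependency and avoided
resource use over the following year. `prehabcea` implements the complete
analysis pipeline for a two-arm randomised trial of this question, and a
synthetic-trial generator with the same statistical structure so that every
stage is testable without access to patient-level data.

## What it computes

For intervention (IG) and control (CG) arms, the package values per-patient
costs in EUR 2019/2020-style societal unit costs over three blocks —
intervention delivery (control arm: 0 by construction), the index hospital
stay (billing + per-case investment reference + expected statutory
co-payment, `0.5 · 10 EUR · min(days, 28)`), and 16-item resource-use
questionnaires at 3, 6, 9 and 12 months (informal care valued by the
substitution cost approach) — and constructs three effect measures:

* **QALY** — the mean of the four quarterly EQ-5D-5L utilities,
  `QALY = (u₃ + u₆ + u₉ + u₁₂)/4`, utilities from a pluggable country value
  set (bounds −0.661 to 1 for the German tariff), with utility 0 from the
  date of death;
* **DCDL** — deterioration in care dependency level (German 0–5 grades),
  dichotomised as `level₁₂ > level₀`, death counting as deterioration
  (level set to 5);
* **WHODAS 2.0** — the 12-item simple score (12 best – 60 worst), 60 at
  death.

Cost blocks are winsorised at their pooled 97.5th percentile (never the
intervention block); missing cells are multiply imputed by chained equations
with predictive-mean-matching draws and combined across imputations at the
individual level before analysis. Incremental results are

    ΔC = mean C(IG) − mean C(CG),   ΔE = mean E(IG) − mean E(CG)

with DCDL and WHODAS differences inverted (lower is better). On the
cost-effectiveness plane, ΔE > 0 with ΔC > 0 yields the ICER = ΔC/ΔE; ΔE > 0
with ΔC < 0 means the intervention dominates; the reverse means the control
dominates. Uncertainty comes from a stratified bootstrap (default 10,000
resamples, arm sizes preserved): percentile confidence intervals, a 95%
confidence ellipse on the plane, and cost-effectiveness acceptability curves
`P(λ·ΔE − ΔC > 0)` over willingness-to-pay λ from 0 to 100,000 EUR.

Analysis populations mirror a full trial analysis matrix: intention-to-treat
(ITT), complete cases (CC), per-protocol with ≥ 15 supervised sessions
(PP15, plus PP15OP requiring surgery) using 1:1 nearest-neighbour
propensity-matched controls, sensitivity analyses without winsorisation
(SA_COSTS) and excluding decedents (SA_EFFECTS), and pre-specified
subgroups (age, sex, surgery type, frailty status, delivery setting,
baseline care level, baseline cognition).

## Worked example

```r
library(prehabcea)

cfg   <- sim_config(n_per_arm = c(300, 290), seed = 2024)
trial <- simulate_trial(cfg)                     # records with MAR dropout
prep  <- cea_prepare(trial, imp = impute_spec(m = 10, iterations = 5,
                                              seed = 2024))
fit   <- cea(prep, effect_kind = "qaly", variant = "ITT",
             B = 5000, seed = 2024)
fit
#> Cost-effectiveness analysis: ITT, effect = qaly
#>   N: 300 IG / 290 CG
#>   Incremental costs: 1,038 EUR (95% CI -584; 2,663)
#>   Incremental effects: 0.03 QALY (95% CI -0.01; 0.06)
#>   ICER: 39,958 EUR per QALY
```

The intervention arm costs 1,038 EUR more per patient and gains 0.03 QALYs;
since both CIs cross zero the ICER of ~40,000 EUR per QALY is uncertain —
`plot(fit)` shows the bootstrap cloud straddling the cost axis, and
`plot(fit, type = "ceac")` the acceptability curve. A matched per-protocol
analysis of the care-dependency effect:

```r
cea(prep, effect_kind = "dcdl", variant = "PP15", B = 5000, seed = 2024)
#> Cost-effectiveness analysis: PP15, effect = dcdl
#>   propensity-score matched population (non-randomised, exploratory)
#>   N: 252 IG / 252 CG
#>   Incremental costs: 1,484 EUR (95% CI -219; 3,210)
#>   Incremental effects: 4.76 percentage points prevented deterioration (95% CI -2.38; 11.9)
#>   ICER: 31,154 EUR per prevented deterioration
```

Adherent patients and their matched controls show a 4.76-percentage-point
reduction in deterioration at ~31,000 EUR per whole prevented case.
`summary()`, `coef()`, `confint()`, `cea_results_table()` and
`cost_overview_table()` give the publication-shaped numbers;
`write_cea()` serialises a results bundle (JSON + bootstrap cloud CSV).

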