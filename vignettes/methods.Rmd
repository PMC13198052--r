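---
title: "Methods: trial-based cost-effectiveness analysis of prehabilitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-effectiveness analysis of prehabilitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`prehabcea` implements a societal-perspective economic evaluation alongside a
two-arm randomised trial of multimodal prehabilitation in elderly (pre-)frail
elective-surgery patients. This vignette documents the model, the numerical
conventions, the synthetic-data generator and the design decisions, in the
order the pipeline runs them.

## The estimand and its construction

The evaluation compares mean per-patient costs and effects between the
intervention arm (frailty screening, a shared decision-making conference and
up to 30 supervised prehabilitation sessions in one of five delivery
settings) and a standard-care control arm, over a 12-month postoperative
horizon. No discounting is applied at this horizon.

**Costs** decompose into three blocks.

* *Intervention*: screening tariff + conference tariff + sessions × a
  setting-specific session tariff. The control arm is identically zero —
  control patients were screened only to determine eligibility. Staff
  training costs are excluded as scale-dependent implementation costs.
* *Index hospital stay*: the hospital bill plus a per-case investment-cost
  reference plus the expected statutory co-payment, `(1 − exempt) × 10 EUR ×
  min(length of stay, 28 days)` with an exemption share of 0.5. The
  exemption enters as a deterministic expected-value multiplier rather than
  per-patient randomisation: the assumption concerns a population share, and
  determinism keeps valuation reproducible. The 28-day calendar-year cap is
  approximated per stay, since no stay-to-calendar mapping is available.
  Patients without surgery have no index stay (cost 0).
* *12-month follow-up*: sixteen resource-use questionnaire items per
  quarterly visit, valued by societal unit costs; informal care is valued by
  the substitution cost approach (the wage of the professional caregiver who
  would otherwise have provided it). Medication use is recorded but carries
  no standardised societal unit cost and is never valued; the category
  exists in the schema and stays empty.

Unit costs and the EQ-5D-5L value set are configuration tables
(`load_unit_costs()`, `load_value_set()`); the bundled defaults are
illustrative, and value-set files declare their best/worst anchors so the
loader can validate the tariff it is given.

**Effects.** The QALY is the arithmetic mean of the four quarterly EQ-5D-5L
utilities; there is no partial-quarter proration because the construction
averages four discrete assessments rather than integrating a continuous
curve. Baseline utility is not part of the QALY but is retained as a
covariate for imputation and matching. Deterioration in care dependency
(DCDL) is the indicator that the 0–5 care grade strictly increased from
baseline to 12 months. WHODAS 2.0 uses 12-item simple scoring (sum, 12–60).

**Death rules.** From the date of death: utility 0 at every assessment on or
after it, all window costs 0, care level 5 (hence deterioration — including
for a patient already at level 5 at baseline, where the death rule takes
precedence over the strict-increase rule), WHODAS 60. These cells are
*determined*, not missing: they are filled before imputation and are never
imputed, and a missing 12-month care level with a known earlier death date
needs no imputation for the same reason. A sensitivity analysis (SA_EFFECTS)
excludes decedents to quantify the influence of the worst-score-at-death
convention.

## Winsorisation

Cost data are heavily right-skewed; a few extreme patients can dominate arm
means. Each cost block is therefore capped at its empirical 97.5th
percentile, computed pooled across both arms (arm-specific thresholds would
treat arms asymmetrically). The quantile uses the linear-interpolation
convention (`stats::quantile` type 7), which is documented because software
conventions differ. The intervention block is never winsorised — it is
tariff-built and has no outliers. The package applies the cap at the
component level (block × visit, plus the index block), because imputation
operates on component-level observables and the main analysis state is
"winsorised and imputed"; winsorisation precedes imputation, and the
no-winsorisation route (SA_COSTS) is a single switch. Totals are always
recomputed from components, so the cost matrix is additive by construction
(block means sum to the total mean, up to print rounding).

## Missing data

Missingness is assumed missing-at-random. Chained-equations multiple
imputation runs over all analysis variables: per-visit utilities (imputed on
the valued utility scale), per-component costs, the 12-month care level and
the WHODAS items. Defaults are m = 20 imputations and 10 sweeps —
conventional values, configurable via `impute_spec()`. Every variable uses
Bayesian predictive-mean-matching draws (donor pool 5): a posterior draw of
the regression coefficients generates predictions for missing rows, which
are matched to the nearest observed predictions and receive a donor's
observed value. Donor draws respect the zero-inflated support of cost
components (pure regression draws would produce negative costs) and the
ordinal supports of care levels and WHODAS items without separate model
code. Predictor sets are restricted for stability: baseline covariates plus
arm for every variable, plus the other visits of the same variable (and the
12-month utility for the 12-month outcomes).

The completed datasets are then **combined at the individual level** before
analysis: continuous cells take the per-cell mean across imputations,
ordinal cells the mode with ties broken toward the worse health state, and
totals and aggregated outcomes (QALY, DCDL, WHODAS) are recomputed from the
combined component-level data — so DCDL is dichotomised from the combined
care level, never averaged as a 0/1 variable. This combination is convenient
but understates between-imputation variance; reported intervals should be
read as lower bounds on uncertainty. `cea(..., combine = "rubin")`
additionally analyses each imputed dataset and pools by Rubin's rules
(within + (1 + 1/m) × between variance, Barnard–Rubin degrees of freedom) as
a comparison, clearly labelled as the non-primary mode.

## Balance and matching

Baseline balance is screened with absolute standardised mean differences
(pooled-SD denominator; binary covariates use the proportion form), flagged
at the conventional 0.10. Per-protocol populations (≥ 15 supervised
sessions; additionally surgery for PP15OP) and the delivery-setting
subgroups require a comparison group, since controls carry no delivery
information: a main-effects logistic propensity model on age, sex, BMI,
comorbidity index, frailty status, baseline care level (dropped when the
outcome is DCDL, to avoid conditioning on the baseline of the outcome
scale), baseline utility, cognition (MOCA total score, continuous), baseline
WHODAS and recruiting specialty (a categorical model term, not a hard
constraint). Matching is greedy 1:1 nearest neighbour without replacement on
the linear predictor, processing treated units in descending score order,
with exact ties broken by a seeded draw, and no caliper by default (an
optional caliper flag exists). Greedy order and tie-breaking are documented
conventions where any choice is defensible. Nearest-neighbour matching on a
score is exactly invariant to affine increasing transforms of that score;
invariance under arbitrary strictly monotone transforms does *not* hold for
distance-based matching (only the score ranks are preserved), which is why
the test suite asserts the affine property and checks the small-sample
optimum by exhaustive assignment enumeration instead. Matched analyses are
labelled non-randomised and exploratory in all outputs.

## Inference

Incremental costs are the IG − CG mean difference; incremental effects
likewise for the QALY, and inverted (CG − IG) for DCDL (reported in
percentage points, i.e. the absolute risk reduction) and WHODAS, because
lower values are preferable there. The verdict follows the plane quadrant;
ICERs divide unrounded ΔC by the unrounded natural-unit ΔE (a whole
prevented deterioration, not a percentage point), and rounding happens only
in the report tables (half-up: EUR to integers, utilities and percentages to
two decimals). A zero ΔE with non-zero ΔC is reported as an undefined ICER
rather than thrown.

Uncertainty: 10,000 bootstrap replicates, resampling patients with
replacement *within arm* with arm sizes preserved (the two-sample design is
part of the estimand). Each replicate re-runs the statistic pipeline —
effect aggregation, mean differences, verdict — on the analysis-ready
combined dataset; imputation and matching define that dataset once and are
not re-run per replicate. Confidence intervals are percentile intervals
whose endpoints are order statistics under the inverse-ECDF convention
(type 1); bias-corrected variants were deliberately not made the default,
as the percentile interval is the simplest defensible reading. The
acceptability curve uses the net-monetary-benefit rule with strict
inequality, `P(λ·ΔE − ΔC > 0)`; at λ = 0 it equals the probability of cost
savings exactly, and it is monotone in λ only when all replicates have
ΔE ≥ 0 (general clouds may be non-monotone; this is documented, not
asserted). The plane ellipse is the bivariate-normal contour at the
chi-square(2) radius around the cloud mean with the cloud covariance;
collinear clouds are flagged degenerate rather than drawn.

## The synthetic-trial generator

`sim_config()` / `generate_trial()` emulate the structure the analysis
assumes. Every patient has a latent disability score `d₀ ~ N(0, 1)`;
baseline covariates correlate with it, EQ-5D-5L dimension levels and WHODAS
items arise by thresholding noisy copies of the current latent state, visits
follow an AR(1) latent trajectory (inducing the visit-to-visit correlation
that chained-equation imputation exploits), and follow-up costs are
zero-inflated gamma per category and visit (medians of zero with heavy right
tails — the regime in which winsorisation matters), tilted by current
disability. Deaths occur with the configured probability, uniformly over the
year (no timing information exists to do better); post-death fields are
structurally truncated, never sampled. Missingness is logistic in age and
baseline WHODAS — observed covariates only, hence MAR with something for
imputation to exploit — with the intercept calibrated in-sample to the
configured marginal rate, plus extra independent masking of the 3-month
EQ-5D-5L, where real follow-up loss concentrated.

Arm effects are injected with closed-form calibration: the intervention
shifts the latent trajectory by the amount that makes the *expected QALY
difference* (through the threshold model and net of the death rule's
zero-utility slots) equal `effect_utility`; survivor deterioration
probabilities are set so the overall (deaths included) CG − IG deterioration
difference equals `effect_dcdl`; and intervention-arm cost means are scaled
so the raw mean follow-up cost difference equals `effect_cost_followup`.
Cost effects are defined on the raw scale: winsorisation compresses
multiplicative shifts, so recovery of the configured cost effect is assessed
on non-winsorised totals. Generator defaults are the study conditions of the
target trial where stated — arm sizes 616/583, ~90% conference attendance,
an adherence distribution putting ~80% of the intervention arm at ≥ 15
sessions, the observed delivery-setting mix, 89% surgery, utility and
deterioration effects at the headline incremental estimates, 7.7% mortality
(implied by the decedent-exclusion arm sizes) — and stated modelling choices
elsewhere: 25% visit missingness with 25% extra 3-month EQ-5D loss, and
zero-inflation/shape parameters chosen once to reproduce the
medians-of-zero, heavy-tail cost pattern. The generator emulates structure,
not the trial's data: real data add recall bias, informative missingness,
COVID-era interruptions, cost-block correlations and value-set specifics the
simulation does not claim, so passing tests demonstrate correctness of the
*procedures*, not reproduction of the trial's point estimates.

## Numerical conventions and degenerate inputs

Quantiles: type 7 for winsorisation and descriptive quartiles; type 1
(order statistics) for bootstrap percentile intervals. Rounding: half-up at
report time only. Ties: ordinal combination ties go to the worse state;
matching ties are seeded draws; age-median subgroup ties go to the older
side. Degenerate inputs: empty cost blocks, arms emptied by filtering,
variables with zero observed values, donor pools smaller than treated pools
and non-converging propensity fits raise errors; a zero-variance imputation
target falls back to donor sampling; a degenerate (collinear) bootstrap
cloud is flagged. All randomness — generation, masking, imputation,
matching tie-breaks, bootstrap — is seeded, and identical configuration plus
seed reproduces results bundles byte-for-byte.

## Problem sizes used in the tests

The shipped test-suite runs use trials of 100–500 patients with light
imputation settings (m = 3–10, 2–5 sweeps) for the orchestration checks,
n = 3,000–5,000 per arm for generator-calibration checks, 200 repetitions ×
2,000 resamples for bootstrap coverage, and exhaustive assignment
enumeration up to 6 treated units as the matching oracle; the acceptance
script runs the full default configuration (616/583 patients, m = 20, 10
sweeps, 10,000 resamples). These sizes are the package's own choice of a
thorough-but-quick default; all are configurable upward.

## Known limitations

Individual-level combination is a variance lower bound (see above). The
matcher is greedy, not optimal (network-flow matching is out of scope); the
small-instance regret against the exhaustive optimum is reported in tests.
The complete-case population is effect-specific (complete costs plus the
cells of the chosen effect), which matches how a per-effect complete-case
analysis behaves but means CC arm sizes differ across effects. ICERs are
reported without ratio-specific confidence intervals (no Fieller
construction); uncertainty is communicated through the plane and the
acceptability curve instead.
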