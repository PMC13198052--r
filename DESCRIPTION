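Package: prehabcea
Title: Trial-Based Cost-Effectiveness Analysis of Prehabilitation from a
    Societal Perspective
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for trial-based economic
    evaluation of multimodal prehabilitation in elderly (pre-)frail
    surgical patients: valuation of intervention, index-hospital-stay and
    twelve-month follow-up resource use into EUR cost blocks;
    quality-adjusted life years from quarterly EQ-5D-5L assessments with
    worst-score-at-death rules; deterioration in care dependency level
    and WHODAS 2.0 effect measures; winsorisation of skewed cost blocks;
    chained-equations multiple imputation with individual-level
    combination; standardised-mean-difference balance checks and 1:1
    nearest-neighbour propensity matching for per-protocol populations;
    and bootstrap inference on the incremental cost-effectiveness plane
    including ICERs, dominance classification, confidence ellipses and
    cost-effectiveness acceptability curves. A synthetic two-arm trial
    generator with configurable arm effects, zero-inflated cost
    distributions, mortality and missing-at-random dropout makes every
    stage testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
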