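# Orchestration tests run on one shared small trial to keep imputation cost
# down; deeper statistical checks live in the module and acceptance suites.

rec_sr <- small_trial(n = c(130, 120), seed = 55, mortality_12m = 0.1)
prep_sr <- small_prep(rec_sr)

test_that("population selection honours each variant's rule", {
  # ITT keeps everyone
  itt <- select_population(prep_sr, "qaly", "ITT")
  expect_equal(nrow(itt$table), nrow(rec_sr))
  expect_false(itt$matched)
  # complete cases: exactly the rows complete for the chosen effect
  cc <- select_population(prep_sr, "qaly", "CC")
  expect_equal(sort(cc$table$id),
               sort(prep_sr$table$id[prehabcea:::complete_rows(prep_sr,
                                                               "qaly")]))
  # effect-specific completeness: the care-dependency effect needs only the
  # 12-month level, so its complete-case set contains the QALY one
  cc_d <- select_population(prep_sr, "dcdl", "CC")
  expect_true(all(cc$table$id %in% cc_d$table$id))
  expect_gte(nrow(cc_d$table), nrow(cc$table))
  # per-protocol: qualifying IG plus equal-sized matched controls
  pp <- select_population(prep_sr, "qaly", "PP15", seed = 3)
  n_qual <- sum(rec_sr$arm == "IG" & rec_sr$sessions >= 15)
  expect_equal(sum(pp$table$arm == "IG"), n_qual)
  expect_equal(sum(pp$table$arm == "CG"), n_qual)
  expect_true(pp$matched)
  expect_equal(length(unique(pp$pairs$donor_id)), n_qual)
  # PP15OP additionally requires surgery
  ppo <- select_population(prep_sr, "qaly", "PP15OP", seed = 3)
  expect_equal(sum(ppo$table$arm == "IG"),
               sum(rec_sr$arm == "IG" & rec_sr$sessions >= 15 &
                     rec_sr$surgery))
  # SA-Effects removes exactly the decedents
  sa <- select_population(prep_sr, "dcdl", "SA_EFFECTS")
  expect_equal(nrow(sa$table), sum(is.na(rec_sr$death_day)))
  expect_error(select_population(prep_sr, "qaly", "SA_EFFECTS"), "dcdl")
})

test_that("partitioning subgroups partition the trial population", {
  for (pair in list(c("age_young", "age_old"), c("sex_f", "sex_m"),
                    c("pre_frail", "frail"),
                    c("care_level_0", "care_level_ge1"),
                    c("moca_normal", "moca_low"))) {
    a <- select_population(prep_sr, "qaly", "ITT", subgroup = pair[1])
    b <- select_population(prep_sr, "qaly", "ITT", subgroup = pair[2])
    expect_equal(sort(c(a$table$id, b$table$id)), sort(prep_sr$table$id))
  }
  # the setting subgroup matches controls to the delivered-setting IG pool
  st <- select_population(prep_sr, "qaly", "ITT",
                          subgroup = "setting_outpatient", seed = 2)
  expect_true(st$matched)
  expect_equal(sum(st$table$arm == "IG"), sum(st$table$arm == "CG"))
  expect_true(all(st$table$setting[st$table$arm == "IG"] %in%
                    c("mobile", "outpatient", "outpatient_transport",
                      "part_inpatient")))
})

test_that("the matching covariate set drops baseline care level for the DCDL effect", {
  expect_true("care_level_0" %in% prehabcea:::match_covariates("qaly"))
  expect_false("care_level_0" %in% prehabcea:::match_covariates("dcdl"))
})

test_that("fits are deterministic and SA-Costs differs from ITT only by the winsorisation switch", {
  f1 <- cea(prep_sr, "qaly", "ITT", B = 400, seed = 9)
  f2 <- cea(prep_sr, "qaly", "ITT", B = 400, seed = 9)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$cloud$delta_cost, f2$cloud$delta_cost)
  expect_identical(f1$ceac, f2$ceac)
  prep_raw <- cea_prepare(rec_sr, winsorise = FALSE,
                          imp = impute_spec(m = 3, iterations = 3,
                                            seed = 5))
  f3 <- cea(prep_raw, "qaly", "SA_COSTS", B = 400, seed = 9)
  m1 <- f1$manifest; m3 <- f3$manifest
  differing <- names(m1)[!mapply(identical, m1, m3)]
  expect_setequal(differing, c("variant", "winsorised"))
})

test_that("deterioration is dichotomised from combined care levels, not averaged as 0/1", {
  fit <- cea(prep_sr, "dcdl", "ITT", B = 200, seed = 1)
  tab <- prep_sr$table
  by_hand <- compute_dcdl(tab$care_level_0, tab$care_level_12m, tab$died)
  ig <- tab$arm == "IG"
  expect_equal(fit$point$mean_effect_ig, mean(by_hand[ig]))
  expect_equal(fit$point$mean_effect_cg, mean(by_hand[!ig]))
  # combined care levels are integers (mode combination), so the indicator
  # is a clean dichotomisation
  expect_true(all(tab$care_level_12m == round(tab$care_level_12m)))
})

test_that("result tables trace back to bundle fields with half-up rounding", {
  fit <- cea(prep_sr, "qaly", "ITT", B = 400, seed = 9)
  tb <- cea_results_table(list(fit))
  expect_equal(tb$n_ig, fit$n_ig)
  expect_equal(tb$delta_cost, round_half_up(fit$point$delta_cost))
  expect_equal(tb$delta_effect, round_half_up(fit$point$delta_effect, 2))
  if (fit$point$verdict == "icer")
    expect_equal(tb$icer, as.character(round_half_up(fit$point$icer)))
  # re-rendering is idempotent
  expect_identical(tb, cea_results_table(list(fit)))
  # dominance renders as text
  dom <- fit
  dom$point$verdict <- "intervention_dominates"
  expect_equal(cea_results_table(list(dom))$icer, "Intervention dominates")
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(2.675, 2), 2.68)
})

test_that("the cost overview enforces additivity of block means", {
  ct <- cost_overview_table(prep_sr)
  blocks <- ct[!ct$block %in% c("total", "followup_total",
                                "intervention", "index_stay"), ]
  for (a in c("ig", "cg")) {
    col <- paste0(a, "_mean")
    fu_sum <- sum(blocks[[col]])
    expect_equal(ct[[col]][ct$block == "followup_total"], fu_sum,
                 tolerance = 2e-3 * max(fu_sum, 1))   # integer rounding only
    expect_equal(ct[[col]][ct$block == "total"],
                 sum(ct[[col]][ct$block %in% c("intervention",
                                               "index_stay",
                                               "followup_total")]),
                 tolerance = 2e-3 * max(fu_sum, 1))
  }
})

test_that("classed fit exposes the standard modelling verbs", {
  fit <- cea(prep_sr, "qaly", "ITT", B = 300, seed = 4)
  expect_named(coef(fit), c("delta_cost", "delta_effect", "icer"))
  ci <- confint(fit)
  expect_equal(unname(ci["delta_cost", ]), fit$ci_cost)
  expect_output(print(fit), "Incremental costs")
  expect_output(summary(fit), "P\\(cost-effective\\)")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
  expect_invisible(plot(fit, type = "ceac"))
})

test_that("Rubin's-rules mode reports pooled uncertainty alongside the primary combination", {
  fit <- cea(prep_sr, "qaly", "ITT", B = 300, seed = 4, combine = "rubin")
  expect_false(is.null(fit$rubin))
  expect_equal(fit$rubin$cost$estimate,
               mean(vapply(prep_sr$imputations, function(d) {
                 o <- prehabcea:::patient_outcomes(d, "qaly")
                 mean(o$total[d$arm == "IG"]) - mean(o$total[d$arm == "CG"])
               }, numeric(1))))
  expect_true(fit$rubin$cost$ci[1] < fit$rubin$cost$ci[2])
})

test_that("results bundles serialise to JSON and cloud CSV", {
  fit <- cea(prep_sr, "qaly", "ITT", B = 200, seed = 4)
  dir <- tempfile()
  paths <- write_cea(fit, dir)
  res <- jsonlite::fromJSON(file.path(dir, "results.json"))
  expect_equal(res$delta_cost, fit$point$delta_cost)
  expect_equal(res$manifest$B, 200)
  cl <- read.csv(file.path(dir, "cloud.csv"))
  expect_equal(nrow(cl), 200)
})
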