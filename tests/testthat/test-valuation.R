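test_that("intervention valuation: control arm is always zero, IG is linear in delivery", {
  uc <- default_unit_costs()
  expect_identical(value_intervention("CG", NA, NA, NA, uc), 0)
  # screening only: no conference, no sessions
  expect_equal(value_intervention("IG", FALSE, 0, NA, uc), 26)
  # full linear composition
  s <- uc[["frailty_screening"]]; d <- uc[["sdm_conference"]]
  cs <- uc[["session_inpatient"]]
  expect_equal(value_intervention("IG", TRUE, 30, "inpatient", uc),
               s + d + 30 * cs)
  expect_error(value_intervention("IG", TRUE, 10, NA, uc), "setting")
  # CG zero across a whole simulated dataset
  rec <- small_trial()
  costs <- value_intervention(rec$arm, rec$sdm, rec$sessions, rec$setting,
                              uc)
  expect_true(all(costs[rec$arm == "CG"] == 0))
  expect_true(all(costs[rec$arm == "IG"] >= 26))
})

test_that("index-stay valuation applies co-payment with cap, zero without surgery", {
  uc <- uc_with(investment_per_case = 0)
  expect_equal(value_index_stay(FALSE, NA, NA, uc), 0)
  expect_equal(value_index_stay(TRUE, 5000, 10, uc), 5000 + 0.5 * 10 * 10)
  # cap binds at 28 days
  expect_equal(value_index_stay(TRUE, 5000, 40, uc) - 5000, 0.5 * 10 * 28)
  # missing bill flags for imputation rather than erroring
  expect_true(is.na(value_index_stay(TRUE, NA, 10, uc)))
})

test_that("follow-up valuation is linear in counts with substitution-cost informal care", {
  uc <- default_unit_costs()
  zeros <- setNames(rep(0, 14), followup_categories())
  expect_true(all(value_followup_visit(zeros, uc) == 0))
  ans <- zeros; ans[["physician_visits"]] <- 2
  expect_equal(value_followup_visit(ans, uc)[["physician_visits"]],
               2 * uc[["physician_visits"]])
  ans <- zeros; ans[["informal_care"]] <- 10
  expect_equal(value_followup_visit(ans, uc)[["informal_care"]],
               10 * uc[["informal_care"]])
  ans[["informal_care"]] <- -1
  expect_error(value_followup_visit(ans, uc), "negative")
  ans[["informal_care"]] <- NA
  expect_true(is.na(value_followup_visit(ans, uc)[["informal_care"]]))
})

test_that("valued components scale homogeneously with the unit-cost table", {
  uc <- default_unit_costs()
  uc2 <- uc; uc2[] <- 3 * unclass(uc)[]
  uc2[["copay_exempt_share"]] <- uc[["copay_exempt_share"]]  # a share, not a price
  ans <- setNames(runif(14, 0, 5), followup_categories())
  expect_equal(value_followup_visit(ans, uc2),
               3 * value_followup_visit(ans, uc))
  expect_equal(value_intervention("IG", TRUE, 12, "outpatient", uc2),
               3 * value_intervention("IG", TRUE, 12, "outpatient", uc))
})

test_that("death zeroing removes windows from the death date onward", {
  fu <- setNames(rep(100, 8),
                 as.vector(outer(c("fu_a_", "fu_b_"),
                                 c("3m", "6m", "9m", "12m"), paste0)))
  alive <- apply_death_zeroing(500, 8000, fu, NA)
  expect_identical(alive$followup, fu)
  # death at month 7 (~day 213): 3m and 6m retained, 9m and 12m zeroed
  d <- apply_death_zeroing(500, 8000, fu, 213)
  expect_equal(unname(d$followup[grepl("3m|6m", names(fu))]), rep(100, 4))
  expect_equal(unname(d$followup[grepl("9m|12m", names(fu))]), rep(0, 4))
  expect_equal(d$index_cost, 8000)
  # death before surgery: index stay and all follow-up zeroed, intervention kept
  d0 <- apply_death_zeroing(500, 8000, fu, -3)
  expect_equal(d0$index_cost, 0)
  expect_true(all(d0$followup == 0))
  expect_equal(d0$intervention, 500)
})

test_that("toy value set hits its anchors and closed form; lookup validates states", {
  vs <- toy_value_set()
  expect_equal(apply_valueset("11111", vs), 1)
  expect_equal(apply_valueset("55555", vs), 0)
  states <- c("12345", "31224", "55515")
  closed <- vapply(states, function(s) {
    lv <- as.integer(strsplit(s, "")[[1]])
    mean(1 - 0.25 * (lv - 1))
  }, numeric(1))
  expect_equal(apply_valueset(states, vs), unname(closed))
  expect_true(is.na(apply_valueset(NA_character_, vs)))
  expect_error(apply_valueset("12346", vs), "malformed")
  expect_error(apply_valueset("1234", vs), "malformed")
})

test_that("value-set files round-trip with declared anchors and reject mismatches", {
  vs <- toy_value_set()
  path <- tempfile(fileext = ".csv")
  writeLines(c("# value set", "# best=11111:1", "# worst=55555:0",
               "state,utility",
               paste(names(vs), unclass(vs), sep = ",")), path)
  vs2 <- load_value_set(path)
  expect_equal(unclass(vs2)[names(vs)], unclass(vs)[names(vs)],
               tolerance = 1e-12, ignore_attr = TRUE)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("# best=11111:0.9", "# worst=55555:0", "state,utility",
               paste(names(vs), unclass(vs), sep = ",")), bad)
  expect_error(load_value_set(bad), "anchor")
})

test_that("unit-cost loader enforces schema coverage", {
  uc <- default_unit_costs()
  expect_s3_class(uc, "unit_cost_table")
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(item = names(uc)[-1], unit = "x",
                       eur = unclass(uc)[-1]), path, row.names = FALSE)
  expect_error(load_unit_costs(path), "lacks entries")
})
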