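# Valuation of resource use, intervention delivery and the index hospital stay
# into EUR cost components (societal perspective).

#' Follow-up resource-use categories
#'
#' The 14 resource-use categories of the 12-month follow-up cost block, one per
#' row of the cost-overview table. Medication use is recorded by the
#' questionnaire but carries no standardised societal unit cost and is never
#' valued; it is therefore not part of this set.
#'
#' @return Character vector of category names.
#' @export
followup_categories <- function() {
  c("hospital_inpatient", "hospital_outpatient", "psychiatry",
    "physician_visits", "therapist_visits", "mobile_nursing",
    "informal_care", "household_assistance", "neighbour_help",
    "day_care", "short_term_care", "nursing_home",
    "rehabilitation", "auxiliary_aids")
}

#' Prehabilitation settings
#' @return Character vector of delivery settings.
#' @export
prehab_settings <- function() {
  c("mobile", "outpatient", "outpatient_transport", "part_inpatient",
    "inpatient")
}

# assessment days of the four follow-up visits (months 3, 6, 9, 12)
visit_days <- function() c(91L, 182L, 274L, 365L)
visit_labels <- function() c("3m", "6m", "9m", "12m")

#' Load a unit-cost table from CSV
#'
#' The CSV schema has three columns: \code{item}, \code{unit} (free-text unit
#' description), \code{eur} (unit cost in EUR, >= 0). Items must cover all
#' follow-up categories plus the intervention tariff items
#' (\code{frailty_screening}, \code{sdm_conference}, one
#' \code{session_<setting>} per prehabilitation setting), the
#' \code{investment_per_case} reference, and the co-payment constants
#' (\code{copay_rate_per_day}, \code{copay_cap_days},
#' \code{copay_exempt_share}).
#'
#' @param path Path to the CSV file.
#' @return A named numeric vector of class \code{"unit_cost_table"}.
#' @export
load_unit_costs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("item", "eur") %in% names(df)))
  uc <- stats::setNames(as.numeric(df$eur), df$item)
  validate_unit_costs(uc)
}

validate_unit_costs <- function(uc) {
  required <- c(followup_categories(),
                paste0("session_", prehab_settings()),
                "frailty_screening", "sdm_conference", "investment_per_case",
                "copay_rate_per_day", "copay_cap_days", "copay_exempt_share")
  missing <- setdiff(required, names(uc))
  if (length(missing))
    stop("unit-cost table lacks entries for: ", paste(missing, collapse = ", "))
  if (any(uc < 0)) stop("unit costs must be non-negative")
  if (uc[["copay_exempt_share"]] > 1)
    stop("copay_exempt_share must lie in [0, 1]")
  class(uc) <- "unit_cost_table"
  uc
}

#' Bundled illustrative unit-cost table
#'
#' German 2020-style societal unit costs are not reprinted here; this bundled
#' table is illustrative and intended for simulation and testing. The frailty
#' screening tariff (26 EUR) and the co-payment constants (10 EUR per day,
#' capped at 28 days, 50\% of patients exempt) are fixed study quantities.
#'
#' @return A \code{"unit_cost_table"}.
#' @export
default_unit_costs <- function() {
  path <- system.file("extdata", "unit_costs_default.csv",
                      package = "prehabcea", mustWork = TRUE)
  load_unit_costs(path)
}

#' Intervention cost of one patient
#'
#' Control-group patients incur no intervention cost (frailty screening was
#' performed for eligibility only and generates no clinical benefit in the
#' control arm). Intervention-group cost is the sum of the frailty screening
#' tariff, the shared decision-making (SDM) conference tariff when the
#' conference took place, and the per-session tariff of the delivery setting
#' times the number of supervised sessions. Transportation is folded into the
#' \code{session_outpatient_transport} tariff. Staff training costs are
#' excluded.
#'
#' @param arm "IG" or "CG" (vectorised).
#' @param sdm Logical, SDM conference held.
#' @param sessions Number of supervised sessions, 0--30.
#' @param setting Delivery setting (one of \code{\link{prehab_settings}}) or
#'   \code{NA} when no prehabilitation was delivered.
#' @param unit_costs A \code{"unit_cost_table"}.
#' @return EUR per patient.
#' @export
value_intervention <- function(arm, sdm, sessions, setting, unit_costs) {
  n <- length(arm)
  sessions[is.na(sessions)] <- 0
  sdm[is.na(sdm)] <- FALSE
  if (any(sessions < 0 | sessions > 30)) stop("sessions must lie in 0..30")
  bad <- arm == "IG" & sessions > 0 &
    (is.na(setting) | !setting %in% prehab_settings())
  if (any(bad)) stop("IG record with sessions > 0 but unknown setting")
  out <- numeric(n)
  ig <- arm == "IG"
  sess_cost <- rep(0, n)
  has_set <- ig & !is.na(setting) & setting %in% prehab_settings()
  sess_cost[has_set] <-
    unname(unit_costs[paste0("session_", setting[has_set])])
  out[ig] <- unit_costs[["frailty_screening"]] +
    sdm[ig] * unit_costs[["sdm_conference"]] +
    sessions[ig] * sess_cost[ig]
  out
}

#' Index hospital stay cost
#'
#' Patients without surgery have no index stay: cost 0. Otherwise the hospital
#' bill is augmented by the per-case investment-cost reference and the expected
#' statutory co-payment, \code{(1 - exempt_share) * rate * min(days, cap)}.
#' The co-payment exemption share enters as a deterministic expected-value
#' multiplier rather than a per-patient random draw. A missing bill with
#' surgery performed yields \code{NA} (flagged for imputation, not an error).
#'
#' @param surgery Logical (vectorised).
#' @param bill Billing total in EUR (\code{NA} when missing).
#' @param los Length of stay in days.
#' @param unit_costs A \code{"unit_cost_table"}.
#' @return EUR per patient (\code{NA} where the bill is missing).
#' @export
value_index_stay <- function(surgery, bill, los, unit_costs) {
  rate <- unit_costs[["copay_rate_per_day"]]
  cap <- unit_costs[["copay_cap_days"]]
  exempt <- unit_costs[["copay_exempt_share"]]
  copay <- (1 - exempt) * rate * pmin(los, cap)
  out <- bill + unit_costs[["investment_per_case"]] + copay
  out[!surgery] <- 0
  out
}

#' Value one three-month recall window of resource-use answers
#'
#' Each reported count (visits, days, hours, items) is multiplied by its
#' societal unit cost. Informal care hours are valued at the professional
#' caregiver substitution wage carried by the unit-cost table. Missing answers
#' propagate as \code{NA} per category.
#'
#' @param answers Named numeric vector (or one-row data frame) of counts with
#'   names in \code{\link{followup_categories}}.
#' @param unit_costs A \code{"unit_cost_table"}.
#' @return Named numeric vector of per-category EUR.
#' @export
value_followup_visit <- function(answers, unit_costs) {
  answers <- unlist(answers)
  cats <- followup_categories()
  stopifnot(all(names(answers) %in% cats))
  if (any(answers < 0, na.rm = TRUE)) stop("negative resource-use counts")
  answers * unname(unit_costs[names(answers)])
}

#' Zero costs from the date of death
#'
#' Cost components attributable to assessment windows on or after the death
#' date are set to 0; earlier components are retained. The index stay is
#' zeroed only when death preceded surgery (negative death day); intervention
#' costs, incurred preoperatively, are always retained.
#'
#' @param intervention,index_cost EUR scalars.
#' @param followup Numeric vector or matrix of follow-up components whose
#'   columns (or names) end in the visit labels \code{3m,6m,9m,12m}.
#' @param death_day Day of death relative to surgery, or \code{NA} if alive.
#' @return List with elements \code{intervention}, \code{index_cost},
#'   \code{followup}.
#' @export
apply_death_zeroing <- function(intervention, index_cost, followup, death_day) {
  if (is.na(death_day))
    return(list(intervention = intervention, index_cost = index_cost,
                followup = followup))
  if (death_day < 0) index_cost <- 0
  labs <- sub(".*_", "", if (is.matrix(followup)) colnames(followup)
              else names(followup))
  dead_visit <- visit_days()[match(labs, visit_labels())] >= death_day
  if (is.matrix(followup)) followup[, dead_visit] <- 0
  else followup[dead_visit] <- 0
  list(intervention = intervention, index_cost = index_cost,
       followup = followup)
}

#' Construct an EQ-5D-5L value set from a state-utility table
#'
#' @param states Character vector of 5-digit states (digits 1--5).
#' @param utilities Numeric utilities.
#' @param best_state,best_utility,worst_state,worst_utility Declared anchors;
#'   validated against the table.
#' @return Named numeric vector of class \code{"value_set"}.
#' @export
value_set <- function(states, utilities,
                      best_state = "11111", best_utility = max(utilities),
                      worst_state = "55555", worst_utility = min(utilities)) {
  states <- as.character(states)
  if (!all(grepl("^[1-5]{5}$", states))) stop("malformed EQ-5D-5L state")
  vs <- stats::setNames(as.numeric(utilities), states)
  if (length(vs) != 3125L) stop("value set must cover all 3,125 states")
  if (abs(vs[[best_state]] - best_utility) > 1e-8 ||
      abs(vs[[worst_state]] - worst_utility) > 1e-8)
    stop("value-set anchors do not match the supplied table")
  if (abs(max(vs) - best_utility) > 1e-8 ||
      abs(min(vs) - worst_utility) > 1e-8)
    stop("table min/max disagree with the declared anchors")
  attr(vs, "anchors") <- c(best = best_utility, worst = worst_utility)
  class(vs) <- "value_set"
  vs
}

#' Load a value set from CSV
#'
#' Schema: columns \code{state} and \code{utility}; anchor declarations in
#' comment header lines of the form \code{# best=11111:1} and
#' \code{# worst=55555:-0.661}.
#'
#' @param path CSV file path.
#' @return A \code{"value_set"}.
#' @export
load_value_set <- function(path) {
  hdr <- grep("^#", readLines(path, n = 10L), value = TRUE)
  parse_anchor <- function(key, default_state) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[1-5]{5}:[-0-9.]+"), hdr))
    m <- unlist(m)
    if (!length(m)) return(NULL)
    parts <- strsplit(sub(paste0(key, "="), "", m[1]), ":")[[1]]
    list(state = parts[1], utility = as.numeric(parts[2]))
  }
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c(state = "character"))
  best <- parse_anchor("best")
  worst <- parse_anchor("worst")
  args <- list(states = df$state, utilities = df$utility)
  if (!is.null(best)) {
    args$best_state <- best$state; args$best_utility <- best$utility
  }
  if (!is.null(worst)) {
    args$worst_state <- worst$state; args$worst_utility <- worst$utility
  }
  do.call(value_set, args)
}

#' Bundled toy value set
#'
#' Each dimension contributes \code{1 - 0.25 * (level - 1)} and the state
#' utility is the mean of the five contributions, so 11111 maps to 1 and 55555
#' to 0. It is an equal-weights stand-in for a country value set, adequate for
#' simulation; analyses of real data should load a published tariff via
#' \code{\link{load_value_set}}.
#'
#' @return A \code{"value_set"}.
#' @export
toy_value_set <- function() {
  grid <- expand.grid(rep(list(1:5), 5))[, 5:1]
  states <- apply(grid, 1, paste0, collapse = "")
  util <- rowMeans(1 - 0.25 * (as.matrix(grid) - 1))
  value_set(states, util, best_state = "11111", best_utility = 1,
            worst_state = "55555", worst_utility = 0)
}

#' Value EQ-5D-5L states to utilities
#'
#' @param eq5d_state Character vector of 5-digit states (NA allowed).
#' @param vs A \code{"value_set"}.
#' @return Numeric utilities (NA propagates).
#' @export
apply_valueset <- function(eq5d_state, vs) {
  stopifnot(inherits(vs, "value_set"))
  out <- rep(NA_real_, length(eq5d_state))
  ok <- !is.na(eq5d_state)
  if (any(!grepl("^[1-5]{5}$", eq5d_state[ok])))
    stop("malformed EQ-5D-5L state")
  idx <- match(eq5d_state[ok], names(vs))
  if (anyNA(idx)) stop("state absent from value set")
  out[ok] <- unname(unclass(vs)[idx])
  out
}
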