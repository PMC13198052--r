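# Orchestration: raw patient records -> valued, death-ruled, winsorised,
# imputed, combined analysis data -> population selection (ITT, complete
# case, per-protocol with matching, sensitivity variants, subgroups) ->
# incremental inference. cea() is the front door and returns a classed fit.

analysis_variants <- function()
  c("ITT", "CC", "PP15", "PP15OP", "SA_COSTS", "SA_EFFECTS")

fu_cols <- function() {
  as.vector(outer(followup_categories(), visit_labels(),
                  function(a, b) paste0("ru_", a, "_", b)))
}
fu_cost_cols <- function() sub("^ru_", "fu_", fu_cols())
u_cols <- function() paste0("u_", visit_labels())
whodas_cols <- function() paste0("whodas12_i", 1:12)

match_covariates <- function(effect_kind) {
  covs <- c("age", "sex", "bmi", "cci", "frailty", "care_level_0", "u_0",
            "moca", "whodas_0", "specialty")
  if (effect_kind == "dcdl") setdiff(covs, "care_level_0") else covs
}

#' Build the analysis-ready dataset
#'
#' Runs the deterministic pipeline stages in order: valuation of
#' intervention, index stay and follow-up resource use into EUR components;
#' EQ-5D-5L valuation to utilities; the worst-score-at-death rules
#' (utilities 0, costs 0 from the date of death, care dependency level 5,
#' WHODAS 60 for decedents - these cells are thereby determined, not
#' missing); winsorisation of the index-stay and follow-up components pooled
#' across arms (never the intervention); chained-equations multiple
#' imputation of the remaining missing cells; and individual-level
#' combination. Totals and aggregated outcomes are computed downstream from
#' the combined component-level data.
#'
#' @param data Patient records (see \code{\link{generate_trial}} for the
#'   schema).
#' @param unit_costs A \code{"unit_cost_table"}.
#' @param vs A \code{"value_set"}.
#' @param winsorise Winsorise cost components (skip for the no-winsorisation
#'   sensitivity analysis).
#' @param percentile Winsorisation percentile.
#' @param impute Run multiple imputation (skip for complete-case use).
#' @param imp An \code{\link{impute_spec}}.
#' @return Object of class \code{"cea_data"}: the combined analysis
#'   \code{table}, the \code{observed} cell mask (TRUE where a value was
#'   known without imputation, including death-determined cells), the
#'   per-imputation completed tables, and the stage flags.
#' @export
cea_prepare <- function(data, unit_costs = default_unit_costs(),
                        vs = toy_value_set(), winsorise = TRUE,
                        percentile = 0.975, impute = TRUE,
                        imp = impute_spec()) {
  need <- c("id", "arm", "age", "sex", "bmi", "cci", "frailty",
            "care_level_0", "moca", "eq5d_0", "whodas_0", "specialty",
            "sdm", "setting", "sessions", "surgery", "index_los",
            "index_bill", "death_day", "care_level_12m",
            paste0("eq5d_", visit_labels()), fu_cols(), whodas_cols())
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("records lack columns: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  tab <- data[setdiff(need, c("eq5d_0", paste0("eq5d_", visit_labels()),
                              "index_bill", fu_cols()))]
  tab$died <- !is.na(data$death_day)

  # valuation
  tab$u_0 <- apply_valueset(data$eq5d_0, vs)
  for (lab in visit_labels())
    tab[[paste0("u_", lab)]] <- apply_valueset(data[[paste0("eq5d_", lab)]],
                                               vs)
  tab$cost_intervention <- value_intervention(data$arm, data$sdm,
                                              data$sessions, data$setting,
                                              unit_costs)
  tab$cost_index <- value_index_stay(data$surgery, data$index_bill,
                                     data$index_los, unit_costs)
  for (cat in followup_categories()) {
    unit <- unit_costs[[cat]]
    for (lab in visit_labels())
      tab[[paste0("fu_", cat, "_", lab)]] <-
        data[[paste0("ru_", cat, "_", lab)]] * unit
  }

  # worst-score-at-death rules: these cells become determined values
  dd <- data$death_day
  for (t in seq_along(visit_labels())) {
    dead_t <- !is.na(dd) & visit_days()[t] >= dd
    tab[dead_t, paste0("u_", visit_labels()[t])] <- 0
    tab[dead_t, paste0("fu_", followup_categories(), "_",
                       visit_labels()[t])] <- 0
  }
  tab$cost_index[!is.na(dd) & dd < 0] <- 0
  tab$care_level_12m[tab$died] <- 5L
  tab[tab$died, whodas_cols()] <- 5

  analysis_vars <- c(u_cols(), "cost_index", fu_cost_cols(),
                     "care_level_12m", whodas_cols())
  observed <- as.data.frame(lapply(tab[analysis_vars],
                                   function(x) !is.na(x)))

  if (winsorise) {
    tab$cost_index <- winsorise_block(tab$cost_index, percentile)
    for (cl in fu_cost_cols())
      tab[[cl]] <- winsorise_block(tab[[cl]], percentile)
  }

  imputations <- NULL
  if (impute && any(!unlist(observed))) {
    base <- c("age", "sex", "bmi", "cci", "frailty", "care_level_0",
              "moca", "u_0", "whodas_0", "arm")
    psets <- list()
    for (lab in visit_labels())
      psets[[paste0("u_", lab)]] <-
        c(base, setdiff(u_cols(), paste0("u_", lab)))
    psets$cost_index <- base
    for (cat in followup_categories()) {
      own <- paste0("fu_", cat, "_", visit_labels())
      for (cl in own) psets[[cl]] <- c(base, setdiff(own, cl))
    }
    psets$care_level_12m <- c(base, "u_12m")
    for (cl in whodas_cols()) psets[[cl]] <- c(base, "u_12m")
    imputations <- impute_dataset(tab, psets, imp)
    tab <- combine_individual(imputations,
                              ordinal = c("care_level_12m", whodas_cols()))
  }
  structure(list(table = tab, observed = observed,
                 imputations = imputations, winsorised = winsorise,
                 percentile = percentile, imputed = impute, imp = imp,
                 unit_costs = unit_costs),
            class = "cea_data")
}

# per-patient total cost and effect vectors from a combined analysis table
patient_outcomes <- function(tab, effect_kind) {
  total <- tab$cost_intervention + tab$cost_index +
    rowSums(as.matrix(tab[fu_cost_cols()]))
  effect <- switch(effect_kind,
    qaly = rowMeans(as.matrix(tab[u_cols()])),
    dcdl = compute_dcdl(tab$care_level_0, tab$care_level_12m, tab$died),
    whodas = ifelse(tab$died, 60, rowSums(as.matrix(tab[whodas_cols()]))))
  list(total = total, effect = effect)
}

complete_rows <- function(prep, effect_kind) {
  obs <- prep$observed
  cost_ok <- obs$cost_index & rowSums(!as.matrix(obs[fu_cost_cols()])) == 0
  eff_ok <- switch(effect_kind,
    qaly = rowSums(!as.matrix(obs[u_cols()])) == 0,
    dcdl = obs$care_level_12m,
    whodas = rowSums(!as.matrix(obs[whodas_cols()])) == 0)
  cost_ok & eff_ok
}

subgroup_labels <- function()
  c("age_young", "age_old", "sex_f", "sex_m", "surgery_ortho_spine",
    "surgery_cardiac", "surgery_tumour", "surgery_other", "pre_frail",
    "frail", "care_level_0", "care_level_ge1", "moca_normal", "moca_low",
    "setting_outpatient", "setting_inpatient")

#' Select the analysis population of a variant and subgroup
#'
#' Applies the subgroup filter first, then the variant rule: ITT and the
#' cost sensitivity analysis keep everyone; the complete-case analysis keeps
#' rows with no missing cost component and no missing cell of the chosen
#' effect (completeness is effect-specific; death-determined cells count as
#' complete); the per-protocol variants keep intervention patients with at
#' least 15 supervised sessions (additionally requiring surgery for PP15OP)
#' plus an equal-sized propensity-matched control group; the effect
#' sensitivity analysis drops decedents (care-dependency and WHODAS effects
#' only). The setting subgroups also trigger matching, since controls carry
#' no delivery information. The age-median split is computed on the analysed
#' dataset with ties going to the older side. Baseline care dependency is
#' excluded from the matching covariates when the effect is deterioration in
#' care dependency.
#'
#' @param prep A \code{\link{cea_prepare}} result.
#' @param effect_kind One of "qaly", "dcdl", "whodas".
#' @param variant One of ITT, CC, PP15, PP15OP, SA_COSTS, SA_EFFECTS.
#' @param subgroup Optional subgroup label (see
#'   \code{prehabcea:::subgroup_labels}).
#' @param seed Seed for matching tie-breaks.
#' @return List: \code{table} (selected rows), \code{matched} (logical),
#'   \code{pairs} (matched-pair table or NULL).
#' @export
select_population <- function(prep, effect_kind, variant = "ITT",
                              subgroup = NULL, seed = 1L) {
  stopifnot(inherits(prep, "cea_data"), variant %in% analysis_variants())
  if (variant == "SA_EFFECTS" && effect_kind == "qaly")
    stop("SA_EFFECTS applies to the dcdl and whodas effects only")
  tab <- prep$table
  keep <- rep(TRUE, nrow(tab))
  treat_extra <- NULL
  if (!is.null(subgroup)) {
    subgroup <- match.arg(subgroup, subgroup_labels())
    keep <- switch(subgroup,
      age_young = tab$age < stats::median(tab$age),
      age_old = tab$age >= stats::median(tab$age),
      sex_f = tab$sex == "F", sex_m = tab$sex == "M",
      surgery_ortho_spine = tab$specialty == "ortho_spine",
      surgery_cardiac = tab$specialty == "cardiac",
      surgery_tumour = tab$specialty == "tumour",
      surgery_other = tab$specialty == "other",
      pre_frail = tab$frailty == "pre-frail",
      frail = tab$frailty == "frail",
      care_level_0 = tab$care_level_0 == 0,
      care_level_ge1 = tab$care_level_0 >= 1,
      moca_normal = tab$moca >= 26, moca_low = tab$moca < 26,
      keep)
    # setting is observed only in the intervention arm: restrict the treated
    # pool and keep the whole control arm as the donor pool for matching
    if (subgroup == "setting_outpatient")
      treat_extra <- !is.na(tab$setting) &
        tab$setting %in% c("mobile", "outpatient", "outpatient_transport",
                           "part_inpatient")
    if (subgroup == "setting_inpatient")
      treat_extra <- !is.na(tab$setting) & tab$setting == "inpatient"
    if (!is.null(treat_extra)) keep <- rep(TRUE, nrow(tab))
  }
  tab <- tab[keep, , drop = FALSE]
  obs_keep <- keep
  if (!is.null(treat_extra)) treat_extra <- treat_extra[keep]

  need_match <- variant %in% c("PP15", "PP15OP") || !is.null(treat_extra)
  if (variant == "CC") {
    tab <- tab[complete_rows(prep, effect_kind)[obs_keep], , drop = FALSE]
  } else if (variant == "SA_EFFECTS") {
    alive <- !tab$died
    tab <- tab[alive, , drop = FALSE]
    if (!is.null(treat_extra)) treat_extra <- treat_extra[alive]
  }
  pairs <- NULL
  if (need_match) {
    treated_sel <- tab$arm == "IG"
    if (variant %in% c("PP15", "PP15OP"))
      treated_sel <- treated_sel & !is.na(tab$sessions) & tab$sessions >= 15
    if (variant == "PP15OP") treated_sel <- treated_sel & tab$surgery
    if (!is.null(treat_extra)) treated_sel <- treated_sel & treat_extra
    treated <- tab[treated_sel, , drop = FALSE]
    donors <- tab[tab$arm == "CG", , drop = FALSE]
    if (!nrow(treated) || !nrow(donors))
      stop("empty arm after per-protocol/subgroup filtering")
    mt <- propensity_match(treated, donors, match_covariates(effect_kind),
                           seed = seed)
    pairs <- data.frame(treated_id = treated$id[mt$pairs$treated],
                        donor_id = donors$id[mt$pairs$donor],
                        distance = mt$pairs$distance)
    tab <- rbind(treated, donors[mt$pairs$donor, , drop = FALSE])
  }
  if (!nrow(tab) || length(unique(tab$arm)) < 2)
    stop("empty arm after population selection")
  list(table = tab, matched = need_match, pairs = pairs)
}

#' Fit a trial-based cost-effectiveness analysis
#'
#' The front door of the package: runs valuation, death rules,
#' winsorisation, imputation, combination, population selection and
#' bootstrap incremental inference on raw patient records, and returns a
#' classed fit with \code{print}, \code{summary}, \code{coef},
#' \code{confint} and \code{plot} methods.
#'
#' @param data Patient records, or a \code{\link{cea_prepare}} result (reuse
#'   one prepared object to fit several effects without re-imputing).
#' @param effect_kind Effect measure: "qaly" (cost-utility), "dcdl"
#'   (deterioration in care dependency level) or "whodas" (WHODAS 2.0 at 12
#'   months).
#' @param variant Analysis population: ITT (imputed, default), CC (complete
#'   cases), PP15 / PP15OP (per-protocol, propensity-matched), SA_COSTS (no
#'   winsorisation), SA_EFFECTS (decedents excluded).
#' @param subgroup Optional subgroup label.
#' @param unit_costs,vs Configuration tables (bundled defaults).
#' @param B Bootstrap resamples (default 10,000).
#' @param seed Seed for imputation, matching tie-breaks and the bootstrap.
#' @param percentile Winsorisation percentile.
#' @param m,iterations Imputation datasets and sweeps.
#' @param combine "individual" (per-cell combination across imputations
#'   before analysis, the primary mode) or "rubin" (additionally pools
#'   per-imputation estimates by Rubin's rules as a variance comparison).
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve.
#' @param conf Confidence level for intervals and the ellipse.
#' @return Object of class \code{"cea"}.
#' @export
cea <- function(data, effect_kind = c("qaly", "dcdl", "whodas"),
                variant = "ITT", subgroup = NULL,
                unit_costs = default_unit_costs(), vs = toy_value_set(),
                B = 10000L, seed = 1L, percentile = 0.975, m = 20L,
                iterations = 10L, combine = c("individual", "rubin"),
                wtp_grid = seq(0, 100000, by = 1000), conf = 0.95) {
  effect_kind <- match.arg(effect_kind)
  combine <- match.arg(combine)
  stopifnot(variant %in% analysis_variants())
  winsorise <- variant != "SA_COSTS"
  if (inherits(data, "cea_data")) {
    prep <- data
    if (prep$winsorised != winsorise)
      stop("prepared data winsorisation does not match variant ", variant)
  } else {
    prep <- cea_prepare(data, unit_costs, vs, winsorise = winsorise,
                        percentile = percentile,
                        impute = variant != "CC",
                        imp = impute_spec(m = m, iterations = iterations,
                                          seed = seed))
  }
  sel <- select_population(prep, effect_kind, variant, subgroup, seed = seed)
  out <- patient_outcomes(sel$table, effect_kind)
  if (anyNA(out$total) || anyNA(out$effect))
    stop("missing analysis values in the selected population; ",
         "run with imputation or use variant = 'CC'")
  arm <- sel$table$arm
  cloud <- bootstrap_cloud(out$total, out$effect, arm, effect_kind,
                           B = B, seed = seed)
  point <- cloud$point
  ci_c <- percentile_ci(cloud$delta_cost, conf)
  ci_e <- percentile_ci(cloud$delta_effect, conf)
  rubin <- NULL
  if (combine == "rubin") {
    if (is.null(prep$imputations))
      stop("combine = 'rubin' needs a prepared object with imputations")
    ids <- sel$table$id
    ests <- lapply(prep$imputations, function(d) {
      di <- d[match(ids, d$id), , drop = FALSE]
      o <- patient_outcomes(di, effect_kind)
      ig <- di$arm == "IG"
      eff <- as.numeric(o$effect)
      list(dc = mean(o$total[ig]) - mean(o$total[!ig]),
           de = delta_effect_natural(mean(eff[ig]), mean(eff[!ig]),
                                     effect_kind),
           vc = stats::var(o$total[ig]) / sum(ig) +
             stats::var(o$total[!ig]) / sum(!ig),
           ve = stats::var(eff[ig]) / sum(ig) +
             stats::var(eff[!ig]) / sum(!ig))
    })
    g <- function(f) vapply(ests, `[[`, numeric(1), f)
    rubin <- list(cost = pool_rubin(g("dc"), g("vc"), conf, length(ids)),
                  effect = pool_rubin(g("de"), g("ve"), conf, length(ids)))
  }
  structure(list(
    effect_kind = effect_kind, variant = variant, subgroup = subgroup,
    matched = sel$matched, pairs = sel$pairs,
    n_ig = sum(arm == "IG"), n_cg = sum(arm == "CG"),
    point = point, ci_cost = ci_c,
    ci_effect = if (effect_kind == "dcdl") 100 * ci_e else ci_e,
    ci_effect_natural = ci_e,
    cloud = cloud, ceac = ceac(cloud, wtp_grid),
    plane = ce_plane(cloud, conf), rubin = rubin,
    manifest = list(variant = variant, effect_kind = effect_kind,
                    subgroup = if (is.null(subgroup)) NA_character_
                               else subgroup,
                    winsorised = winsorise,
                    percentile = percentile,
                    imputed = prep$imputed, m = prep$imp$m,
                    iterations = prep$imp$iterations,
                    B = as.integer(B), seed = as.integer(seed),
                    conf = conf, matched = sel$matched,
                    n_ig = sum(arm == "IG"), n_cg = sum(arm == "CG"))),
    class = "cea")
}

#' Round half away from zero
#'
#' Reporting convention for the result tables (EUR to integers, utilities
#' and percentages to two decimals): halves round up in magnitude, unlike
#' base \code{round}'s round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

block_stats <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(mean = mean(x), sd = stats::sd(x), median = q[2], q1 = q[1], q3 = q[3])
}

#' Cost-overview table (one row per cost block, both arms)
#'
#' Mean, SD, median and quartiles of every cost block per arm, in EUR
#' rounded half-up to integers: intervention, index stay, each follow-up
#' category (annual), the follow-up block total and the total costs.
#'
#' @param prep A \code{\link{cea_prepare}} result (combined data).
#' @return Data frame.
#' @export
cost_overview_table <- function(prep) {
  tab <- prep$table
  fu <- as.matrix(tab[fu_cost_cols()])
  blocks <- c(list(intervention = tab$cost_intervention,
                   index_stay = tab$cost_index),
              stats::setNames(lapply(followup_categories(), function(cat)
                rowSums(fu[, paste0("fu_", cat, "_", visit_labels()),
                           drop = FALSE])), followup_categories()),
              list(followup_total = rowSums(fu),
                   total = tab$cost_intervention + tab$cost_index +
                     rowSums(fu)))
  rows <- lapply(names(blocks), function(b) {
    out <- data.frame(block = b)
    for (a in c("IG", "CG")) {
      s <- block_stats(blocks[[b]][tab$arm == a])
      names(s) <- paste0(tolower(a), "_", names(s))
      out <- cbind(out, as.data.frame(as.list(round_half_up(s))))
    }
    out
  })
  do.call(rbind, rows)
}

#' Results table across analyses
#'
#' One row per fitted analysis in the shape of the published cost-utility /
#' cost-effectiveness tables: arm sizes, mean (SD) costs, incremental costs
#' with bootstrap CI, mean (SD) effects (count and percentage for the
#' care-dependency effect), incremental effects with CI, and the ICER or
#' dominance label. EUR are rounded half-up to integers, utilities and
#' percentages to two decimals; the ICER is computed from unrounded values
#' and rounded only here.
#'
#' @param fits List of \code{\link{cea}} objects (same effect kind).
#' @return Data frame.
#' @export
cea_results_table <- function(fits) {
  if (inherits(fits, "cea")) fits <- list(fits)
  rows <- lapply(fits, function(x) {
    p <- x$point
    eff_digits <- if (x$effect_kind == "qaly") 2 else 2
    icer_cell <- switch(p$verdict,
      icer = as.character(round_half_up(p$icer)),
      intervention_dominates = "Intervention dominates",
      control_dominates = "Control dominates",
      undefined_icer = "Undefined (zero incremental effect)")
    if (p$verdict == "icer" && p$quadrant == "south-west")
      icer_cell <- paste0(icer_cell, " (south-west)")
    out <- data.frame(
      analysis = paste0(x$variant,
                        if (!is.null(x$subgroup))
                          paste0(":", x$subgroup) else ""),
      effect_kind = x$effect_kind,
      n_ig = x$n_ig, n_cg = x$n_cg,
      cost_ig_mean = round_half_up(p$mean_cost_ig),
      cost_ig_sd = round_half_up(p$sd_cost_ig),
      cost_cg_mean = round_half_up(p$mean_cost_cg),
      cost_cg_sd = round_half_up(p$sd_cost_cg),
      delta_cost = round_half_up(p$delta_cost),
      delta_cost_lo = round_half_up(x$ci_cost[1]),
      delta_cost_hi = round_half_up(x$ci_cost[2]),
      stringsAsFactors = FALSE)
    if (x$effect_kind == "dcdl") {
      out$effect_ig_n <- round_half_up(p$mean_effect_ig * x$n_ig)
      out$effect_ig_pct <- round_half_up(100 * p$mean_effect_ig, 2)
      out$effect_cg_n <- round_half_up(p$mean_effect_cg * x$n_cg)
      out$effect_cg_pct <- round_half_up(100 * p$mean_effect_cg, 2)
    } else {
      out$effect_ig_mean <- round_half_up(p$mean_effect_ig, eff_digits)
      out$effect_ig_sd <- round_half_up(p$sd_effect_ig, eff_digits)
      out$effect_cg_mean <- round_half_up(p$mean_effect_cg, eff_digits)
      out$effect_cg_sd <- round_half_up(p$sd_effect_cg, eff_digits)
    }
    out$delta_effect <- round_half_up(p$delta_effect, 2)
    out$delta_effect_lo <- round_half_up(x$ci_effect[1], 2)
    out$delta_effect_hi <- round_half_up(x$ci_effect[2], 2)
    out$icer <- icer_cell
    out
  })
  same <- unique(vapply(rows, function(r) r$effect_kind, ""))
  if (length(same) > 1)
    warning("mixing effect kinds in one results table")
  do.call(rbind, rows)
}

#' Write a results bundle to disk
#'
#' Results JSON (point estimates, intervals, verdict, acceptability table,
#' manifest) plus the bootstrap cloud as CSV.
#'
#' @param x A \code{\link{cea}} fit.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_cea <- function(x, dir) {
  stopifnot(inherits(x, "cea"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- x$point
  res <- list(manifest = x$manifest,
              delta_cost = p$delta_cost, ci_cost = x$ci_cost,
              delta_effect = p$delta_effect, ci_effect = x$ci_effect,
              icer = p$icer, verdict = p$verdict, quadrant = p$quadrant,
              ceac = x$ceac)
  json <- file.path(dir, "results.json")
  writeLines(jsonlite::toJSON(res, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns", na = "null"), json)
  cloud_csv <- file.path(dir, "cloud.csv")
  utils::write.csv(data.frame(delta_cost = x$cloud$delta_cost,
                              delta_effect = x$cloud$delta_effect),
                   cloud_csv, row.names = FALSE)
  invisible(c(json, cloud_csv))
}
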