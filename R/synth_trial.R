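# Synthetic two-arm prehabilitation trial generator.
#
# Every patient carries a latent disability score d0 ~ N(0,1); baseline
# covariates, EQ-5D-5L states, WHODAS items, care dependency and follow-up
# costs are all derived from it, which (a) induces the visit-to-visit
# correlation chained-equation imputation needs and (b) lets arm effects be
# calibrated in closed form: the intervention shifts the latent trajectory by
# an amount solved so that the expected arm difference equals the configured
# effect exactly, after accounting for the worst-score-at-death rules.

# latent-model constants: dimension thresholds chosen so that baseline
# utility under the toy value set averages ~0.75 and baseline WHODAS ~23
EQ5D_CUTS <- c(-0.5, 0.9, 1.8, 2.8)
EQ5D_DIM_SD <- 0.5
WHODAS_CUTS <- c(-0.3, 0.8, 1.8, 2.8)
WHODAS_ITEM_SD <- 0.6
LATENT_LOAD <- 0.8       # d_t = LOAD * d0 + drift + arm shift + w_t
LATENT_W_SD <- 0.6       # so marginal sd of d_t stays 1
LATENT_AR <- 0.7
POSTOP_DRIFT <- 0.15     # slight average worsening after surgery

#' Simulation configuration for a synthetic two-arm trial
#'
#' Defaults are the study conditions of the trial the pipeline targets: arm
#' sizes 616/583, a mean utility gain of 0.0264 (the incremental QALY implied
#' by the headline cost-utility result), a 4.42-percentage-point reduction in
#' deterioration of care dependency, an 855 EUR reduction in mean follow-up
#' cost, 7.7\% twelve-month mortality, and heavy visit-level missingness with
#' extra loss of the 3-month EQ-5D-5L.
#'
#' @param n_per_arm Patients per arm; scalar or length-2 \code{c(IG, CG)}.
#' @param seed Integer seed; the generator is byte-reproducible given the
#'   config and seed.
#' @param effect_utility Expected IG-CG difference in mean QALY (utility
#'   units), net of the death rule.
#' @param effect_dcdl Expected CG-IG difference in the overall deterioration
#'   probability (deaths included), as a proportion.
#' @param effect_cost_followup Expected IG-CG difference in mean 12-month
#'   follow-up cost (EUR), net of death zeroing.
#' @param mortality_12m Probability of death within the year (either arm);
#'   death day uniform over the year.
#' @param missing_visit_prob Marginal probability a follow-up visit is
#'   missing (missing-at-random, logistic in age and baseline WHODAS).
#' @param missing_3m_extra Additional independent masking probability for the
#'   3-month EQ-5D-5L.
#' @param cost_block_params Data frame with columns \code{category},
#'   \code{p_zero} (per-visit zero-inflation), \code{shape} (gamma shape),
#'   \code{mean_annual} (target mean annual EUR in the control arm).
#' @param setting_mix Named probabilities over the prehabilitation settings.
#' @param adherence_dist Probabilities over supervised session counts 0--30.
#' @param surgery_prob Probability of undergoing the index surgery.
#' @param sdm_prob Probability an IG patient receives the shared
#'   decision-making conference.
#' @param dcdl_base_cg Survivor deterioration probability in the CG.
#' @return Object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_per_arm = c(616L, 583L),
                       seed = 1L,
                       effect_utility = 0.0264,
                       effect_dcdl = 0.0442,
                       effect_cost_followup = -855,
                       mortality_12m = 0.077,
                       missing_visit_prob = 0.25,
                       missing_3m_extra = 0.25,
                       cost_block_params = default_cost_block_params(),
                       setting_mix = c(mobile = 0.008, outpatient = 0.133,
                                       outpatient_transport = 0.661,
                                       part_inpatient = 0.044,
                                       inpatient = 0.154),
                       adherence_dist = default_adherence_dist(),
                       surgery_prob = 0.89,
                       sdm_prob = 0.90,
                       dcdl_base_cg = 0.17) {
  n_per_arm <- as.integer(rep_len(n_per_arm, 2L))
  if (any(n_per_arm < 2L)) stop("n_per_arm must be >= 2")
  probs <- c(mortality_12m, missing_visit_prob, missing_3m_extra,
             surgery_prob, sdm_prob, dcdl_base_cg, setting_mix,
             adherence_dist)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(setting_mix) - 1) > 1e-8) stop("setting_mix must sum to 1")
  if (abs(sum(adherence_dist) - 1) > 1e-8)
    stop("adherence_dist must sum to 1")
  stopifnot(identical(sort(names(setting_mix)), sort(prehab_settings())),
            length(adherence_dist) == 31L,
            all(followup_categories() %in% cost_block_params$category))
  structure(list(n_per_arm = n_per_arm, seed = as.integer(seed),
                 effect_utility = effect_utility, effect_dcdl = effect_dcdl,
                 effect_cost_followup = effect_cost_followup,
                 mortality_12m = mortality_12m,
                 missing_visit_prob = missing_visit_prob,
                 missing_3m_extra = missing_3m_extra,
                 cost_block_params = cost_block_params,
                 setting_mix = setting_mix,
                 adherence_dist = adherence_dist,
                 surgery_prob = surgery_prob, sdm_prob = sdm_prob,
                 dcdl_base_cg = dcdl_base_cg),
            class = "sim_config")
}

#' Default zero-inflated gamma parameters for the follow-up cost blocks
#'
#' Point mass at zero plus a gamma component per category and visit,
#' reproducing the medians-of-zero, heavy-right-tail pattern of societal
#' follow-up cost data (which is what makes winsorisation matter). Mean
#' annual EUR targets are control-arm values.
#'
#' @return Data frame with columns \code{category}, \code{p_zero},
#'   \code{shape}, \code{mean_annual}.
#' @export
default_cost_block_params <- function() {
  data.frame(
    category = followup_categories(),
    p_zero = c(0.75, 0.92, 1.00, 0.10, 0.35, 0.85, 0.85, 0.90, 0.88,
               1.00, 1.00, 0.97, 0.70, 0.55),
    shape = c(0.5, 0.8, 0.8, 1.2, 0.8, 0.6, 0.5, 0.8, 0.6, 0.8, 0.8,
              0.5, 0.9, 0.9),
    mean_annual = c(5875, 138, 0, 689, 715, 886, 2879, 103, 435, 0, 0,
                    137, 1754, 238))
}

#' Default distribution of supervised session counts (0--30)
#'
#' 16\% of intervention patients never start; attenders cluster near the full
#' 30-session programme (counts 30 - k with k negative binomial), putting
#' roughly 80\% of the arm at 15 or more sessions.
#'
#' @return Probability vector of length 31 (counts 0..30).
#' @export
default_adherence_dist <- function() {
  p0 <- 0.16
  w <- stats::dnbinom(30:1 - 1, size = 1.5, mu = 4)
  c(p0, (1 - p0) * w / sum(w))
}

# expected fraction of the four quarterly assessments occurring before death,
# with death uniform over (0, 365]
alive_visit_fraction <- function() mean((365 - visit_days()) / 365)

# expected toy-value-set utility of one visit when the latent disability mean
# is mu (marginal latent sd 1, dimension noise sd EQ5D_DIM_SD)
expected_utility <- function(mu) {
  s <- sqrt(1 + EQ5D_DIM_SD^2)
  1 - 0.25 * sum(stats::pnorm((mu - EQ5D_CUTS) / s))
}

# latent arm shift delta such that the expected QALY difference (IG - CG),
# including the death rule's zero-utility slots, equals effect_utility
solve_latent_shift <- function(effect_utility, mortality) {
  if (effect_utility == 0) return(0)
  kappa <- (1 - mortality) + mortality * alive_visit_fraction()
  target <- effect_utility / kappa
  mu_cg <- POSTOP_DRIFT
  stats::uniroot(function(d) expected_utility(mu_cg + d) -
                   expected_utility(mu_cg) - target,
                 interval = c(-4, 4), tol = 1e-10)$root
}

# intercept a such that mean(plogis(a + x)) over the supplied latent values
# equals target (in-sample calibration of logistic mechanisms)
solve_logistic_intercept <- function(x, target) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  stats::uniroot(function(a) mean(stats::plogis(a + x)) - target,
                 interval = c(-20, 20), tol = 1e-10)$root
}

#' Generate a complete synthetic trial
#'
#' Returns one row per patient with baseline covariates, intervention
#' delivery, index-stay billing, per-visit EQ-5D-5L states and resource-use
#' answers, 12-month care dependency and WHODAS items, and death day. Arm
#' assignment is independent of all baseline covariates (randomisation).
#' Fields dated after death are \code{NA}: they are structurally determined
#' by the worst-score-at-death rules downstream, never sampled, and never
#' treated as missing data. Records are complete apart from death
#' truncation; apply \code{\link{apply_missingness}} for the
#' missing-at-random dropout of the observed trial.
#'
#' @param config A \code{\link{sim_config}}.
#' @return Data frame of patient records, with the config in
#'   \code{attr(, "sim_config")}.
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_ig <- config$n_per_arm[1]; n_cg <- config$n_per_arm[2]
  n <- n_ig + n_cg
  arm <- rep(c("IG", "CG"), c(n_ig, n_cg))
  ig <- arm == "IG"

  # latent disability and correlated baseline covariates
  d0 <- stats::rnorm(n)
  age <- pmin(95, pmax(70, round(78 + 5 * (0.35 * d0 +
                                             sqrt(1 - 0.35^2) * stats::rnorm(n)))))
  sex <- ifelse(stats::runif(n) < 0.545, "F", "M")
  bmi <- round(pmax(16, 27 + 4.5 * stats::rnorm(n)), 1)
  cci <- pmin(14, pmax(0, round(5 + 1.5 * (0.3 * d0 +
                                             sqrt(1 - 0.3^2) * stats::rnorm(n)))))
  frailty <- ifelse(stats::plogis(-0.65 + 0.5 * d0) > stats::runif(n),
                    "frail", "pre-frail")
  moca <- pmin(30, pmax(5, round(23.5 + 3.5 * (-0.3 * d0 +
                                                 sqrt(1 - 0.3^2) * stats::rnorm(n)))))
  specialty <- sample(c("ortho_spine", "cardiac", "tumour", "other"), n,
                      replace = TRUE, prob = c(0.53, 0.10, 0.08, 0.29))
  surgical_risk <- sample(c("low", "intermediate", "high"), n, replace = TRUE,
                          prob = c(0.35, 0.45, 0.20))
  # baseline care dependency level from cumulative normal thresholds matching
  # the observed marginal distribution (majority at level 0)
  cl_cuts <- stats::qnorm(cumsum(c(0.742, 0.155, 0.067, 0.032, 0.003))[1:5])
  care_level_0 <- rowSums(outer(d0, cl_cuts, ">"))

  eq5d_state <- function(lat) {
    lv <- sapply(1:5, function(k)
      1 + rowSums(outer(lat + stats::rnorm(length(lat), 0, EQ5D_DIM_SD),
                        EQ5D_CUTS, ">")))
    apply(lv, 1, paste0, collapse = "")
  }
  whodas_items <- function(lat) {
    sapply(1:12, function(k)
      1 + rowSums(outer(lat + stats::rnorm(length(lat), 0, WHODAS_ITEM_SD),
                        WHODAS_CUTS, ">")))
  }
  eq5d_0 <- eq5d_state(d0)
  whodas_0 <- rowSums(whodas_items(d0))

  # intervention delivery
  sdm <- ifelse(ig, stats::runif(n) < config$sdm_prob, NA)
  sessions <- ifelse(ig, sample(0:30, n, replace = TRUE,
                                prob = config$adherence_dist), NA_integer_)
  setting <- rep(NA_character_, n)
  got <- ig & !is.na(sessions) & sessions > 0
  setting[got] <- sample(names(config$setting_mix), sum(got), replace = TRUE,
                         prob = config$setting_mix)

  # index surgery and billing
  surgery <- stats::runif(n) < config$surgery_prob
  index_los <- ifelse(surgery, 1 + round(stats::rgamma(n, 2, scale = 5.5)),
                      NA_real_)
  index_bill <- ifelse(surgery, round(stats::rgamma(n, 1.6, scale = 6000), 2),
                       NA_real_)

  # mortality, uniform over the year
  died <- stats::runif(n) < config$mortality_12m
  death_day <- ifelse(died, sample.int(365, n, replace = TRUE), NA_integer_)

  # latent disability trajectory over the four visits (AR(1) innovations),
  # with the intervention shifting the IG mean by the calibrated delta
  delta <- solve_latent_shift(config$effect_utility, config$mortality_12m)
  mu <- POSTOP_DRIFT + ifelse(ig, delta, 0)
  w <- matrix(0, n, 4)
  w[, 1] <- stats::rnorm(n, 0, LATENT_W_SD)
  for (t in 2:4)
    w[, t] <- LATENT_AR * w[, t - 1] +
      sqrt(1 - LATENT_AR^2) * stats::rnorm(n, 0, LATENT_W_SD)
  d_t <- LATENT_LOAD * d0 + mu + w    # n x 4

  alive_at <- function(t) is.na(death_day) | death_day > visit_days()[t]
  rec <- data.frame(id = seq_len(n), arm = arm, age = age, sex = sex,
                    bmi = bmi, cci = cci, frailty = frailty,
                    care_level_0 = care_level_0, moca = moca,
                    eq5d_0 = eq5d_0, whodas_0 = whodas_0,
                    specialty = specialty, surgical_risk = surgical_risk,
                    sdm = sdm, setting = setting, sessions = sessions,
                    surgery = surgery, index_los = index_los,
                    index_bill = index_bill, death_day = death_day,
                    stringsAsFactors = FALSE)

  for (t in 1:4) {
    st <- eq5d_state(d_t[, t])
    st[!alive_at(t)] <- NA_character_
    rec[[paste0("eq5d_", visit_labels()[t])]] <- st
  }

  # follow-up resource use: zero-inflated gamma EUR per category-visit,
  # tilted by current latent disability, expressed as counts via unit costs
  uc <- default_unit_costs()
  cbp <- config$cost_block_params
  kappa <- (1 - config$mortality_12m) +
    config$mortality_12m * alive_visit_fraction()
  cg_total <- sum(cbp$mean_annual)
  f_ig <- if (cg_total > 0)
    1 + (config$effect_cost_followup / kappa) / cg_total else 1
  if (f_ig <= 0) stop("effect_cost_followup implies non-positive IG costs")
  tilt <- exp(0.35 * d_t)
  tilt <- sweep(tilt, 1, exp(0.35 * mu + 0.5 * 0.35^2), "/")
  for (ci in seq_len(nrow(cbp))) {
    cat <- cbp$category[ci]
    m_visit <- cbp$mean_annual[ci] / 4
    if (cbp$p_zero[ci] < 1 && m_visit > 0) {
      g_mean <- m_visit / (1 - cbp$p_zero[ci])
    } else g_mean <- 0
    for (t in 1:4) {
      eur <- numeric(n)
      if (g_mean > 0) {
        nz <- stats::runif(n) >= cbp$p_zero[ci]
        mean_i <- g_mean * tilt[, t] * ifelse(ig, f_ig, 1)
        eur[nz] <- stats::rgamma(sum(nz), shape = cbp$shape[ci],
                                 scale = mean_i[nz] / cbp$shape[ci])
      }
      cnt <- round(eur / uc[[cat]], 2)
      cnt[!alive_at(t)] <- NA_real_
      rec[[paste0("ru_", cat, "_", visit_labels()[t])]] <- cnt
    }
  }

  # 12-month care dependency (survivors); deterioration logistic in d0 with
  # the marginal rate calibrated per arm so the overall (deaths included)
  # CG-IG difference equals effect_dcdl
  p_cg <- config$dcdl_base_cg
  p_ig <- p_cg - config$effect_dcdl / (1 - config$mortality_12m)
  if (p_ig < 0 || p_ig > 1) stop("effect_dcdl incompatible with dcdl_base_cg")
  prob <- numeric(n)
  for (a in c("IG", "CG")) {
    tgt <- if (a == "IG") p_ig else p_cg
    sel <- arm == a
    a0 <- solve_logistic_intercept(0.7 * d0[sel], tgt)
    prob[sel] <- stats::plogis(a0 + 0.7 * d0[sel])
  }
  det <- stats::runif(n) < prob
  step <- sample(1:2, n, replace = TRUE, prob = c(0.7, 0.3))
  care_level_12m <- ifelse(det, pmin(5, care_level_0 + step), care_level_0)
  care_level_12m[died] <- NA_integer_   # death rule applies downstream
  rec$care_level_12m <- as.integer(care_level_12m)

  w12 <- whodas_items(d_t[, 4])
  w12[died, ] <- NA_real_
  colnames(w12) <- paste0("whodas12_i", 1:12)
  rec <- cbind(rec, as.data.frame(w12))

  attr(rec, "sim_config") <- config
  rec
}

#' Mask visits missing-at-random
#'
#' Each follow-up visit of each survivor-observable patient is masked with a
#' probability that is logistic in age and baseline WHODAS (both observed
#' baseline covariates; the mechanism never depends on the masked values
#' themselves), with the intercept calibrated in-sample so the marginal
#' masking rate equals \code{missing_visit_prob}. A masked visit loses its
#' EQ-5D-5L state and all resource-use answers; a masked 12-month visit also
#' loses the care dependency level and the WHODAS items. The 3-month
#' EQ-5D-5L is additionally masked with independent probability
#' \code{missing_3m_extra}. Death-truncated fields are already \code{NA} by
#' construction and are not additionally masked.
#'
#' @param records Output of \code{\link{generate_trial}}.
#' @param config The \code{\link{sim_config}} (its seed, offset by one, seeds
#'   the masking).
#' @return The records with masked entries set to \code{NA}.
#' @export
apply_missingness <- function(records, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- nrow(records)
  x <- 0.4 * scale(records$age)[, 1] + 0.3 * scale(records$whodas_0)[, 1]
  a0 <- solve_logistic_intercept(x, config$missing_visit_prob)
  p <- stats::plogis(a0 + x)
  ru_cols <- function(t) paste0("ru_", followup_categories(), "_", t)
  for (t in seq_along(visit_labels())) {
    lab <- visit_labels()[t]
    alive <- is.na(records$death_day) | records$death_day > visit_days()[t]
    miss <- alive & stats::runif(n) < p
    records[miss, paste0("eq5d_", lab)] <- NA_character_
    records[miss, ru_cols(lab)] <- NA_real_
    if (lab == "12m") {
      records$care_level_12m[miss] <- NA_integer_
      records[miss, paste0("whodas12_i", 1:12)] <- NA_real_
    }
    if (lab == "3m") {
      extra <- alive & stats::runif(n) < config$missing_3m_extra
      records$eq5d_3m[extra] <- NA_character_
    }
  }
  attr(records, "sim_config") <- config
  records
}

#' Generate a synthetic trial with missing-at-random dropout
#'
#' Convenience composition of \code{\link{generate_trial}} and
#' \code{\link{apply_missingness}}.
#'
#' @param config A \code{\link{sim_config}}.
#' @return Data frame of patient records.
#' @export
simulate_trial <- function(config) {
  apply_missingness(generate_trial(config), config)
}

#' Write a trial to disk
#'
#' Writes the canonical wide patient-record CSV plus a JSON sidecar of the
#' simulation configuration used.
#'
#' @param records Patient-record data frame.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_trial <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "trial.csv")
  utils::write.csv(records, csv, row.names = FALSE)
  paths <- csv
  cfg <- attr(records, "sim_config")
  if (!is.null(cfg)) {
    js <- file.path(dir, "sim_config.json")
    writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                digits = NA, dataframe = "columns"), js)
    paths <- c(paths, js)
  }
  invisible(paths)
}

#' Read a trial written by \code{\link{write_trial}}
#'
#' @param path Path to the trial CSV.
#' @return Patient-record data frame.
#' @export
read_trial <- function(path) {
  eqc <- c("eq5d_0", paste0("eq5d_", visit_labels()))
  cls <- stats::setNames(rep("character", length(eqc) + 3),
                         c(eqc, "arm", "sex", "frailty"))
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = cls)
}
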