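# Shared fixtures: small trials and hand-built records, all generated in
# code at test time.

small_trial <- function(n = c(120, 110), seed = 101, ...) {
  simulate_trial(sim_config(n_per_arm = n, seed = seed, ...))
}

# a prepared small analysis dataset (light imputation settings for speed)
small_prep <- function(rec, winsorise = TRUE, m = 3, iterations = 3,
                       seed = 5) {
  cea_prepare(rec, winsorise = winsorise,
              imp = impute_spec(m = m, iterations = iterations,
                                seed = seed))
}

# unit-cost table with chosen entries overridden
uc_with <- function(...) {
  uc <- default_unit_costs()
  over <- list(...)
  for (nm in names(over)) uc[[nm]] <- over[[nm]]
  uc
}

# exhaustive-minimum total distance for 1:1 assignment of treated scores to
# donor scores (oracle for the greedy matcher; feasible for <= 6 treated)
oracle_assignment <- function(score_t, score_d) {
  nt <- length(score_t)
  perms <- function(v) {
    if (length(v) <= 1) return(matrix(v, ncol = length(v)))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], perms(v[-i]))))
  }
  subsets <- utils::combn(seq_along(score_d), nt)
  best <- Inf
  for (j in seq_len(ncol(subsets))) {
    for (k in seq_len(nrow(perms(subsets[, j])))) {
      asg <- perms(subsets[, j])[k, ]
      tot <- sum(abs(score_t - score_d[asg]))
      if (tot < best) best <- tot
    }
  }
  best
}
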