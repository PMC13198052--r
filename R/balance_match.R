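# Baseline balance via standardised mean differences and 1:1 greedy
# nearest-neighbour propensity-score matching for the per-protocol and
# setting analyses (needed because control patients carry no delivery
# information). Matched analyses are non-randomised and exploratory.

#' Standardised mean difference between two groups
#'
#' Continuous: \code{|mean_a - mean_b| / sqrt((var_a + var_b) / 2)}.
#' Binary: \code{|p_a - p_b| / sqrt((p_a(1-p_a) + p_b(1-p_b)) / 2)}.
#' The absolute value is reported. An SMD of 0.10 or more conventionally
#' flags imbalance needing adjustment.
#'
#' @param a,b Numeric (or logical, for binary) vectors for the two groups.
#' @param type "continuous" or "binary".
#' @return Non-negative SMD as a fraction.
#' @export
smd <- function(a, b, type = c("continuous", "binary")) {
  type <- match.arg(type)
  a <- as.numeric(a); b <- as.numeric(b)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (type == "continuous") {
    stopifnot(length(a) >= 2, length(b) >= 2)
    denom <- sqrt((stats::var(a) + stats::var(b)) / 2)
  } else {
    pa <- mean(a); pb <- mean(b)
    denom <- sqrt((pa * (1 - pa) + pb * (1 - pb)) / 2)
  }
  num <- abs(mean(a) - mean(b))
  if (denom == 0) {
    if (num == 0) return(0)
    stop("zero pooled variance with unequal means")
  }
  num / denom
}

#' Covariate balance report
#'
#' Computes the absolute SMD of each covariate between the two arms. Numeric
#' covariates are treated as continuous; logical and two-level categorical
#' covariates as binary; a categorical covariate with more than two levels
#' reports the largest SMD over its level indicators.
#'
#' @param data Data frame.
#' @param covariates Character vector of covariate columns.
#' @param group Name of the two-level grouping column (default "arm").
#' @param threshold Flagging cut-off (default 0.10).
#' @return Data frame with columns \code{covariate}, \code{smd},
#'   \code{flagged}; \code{attr(, "needs_adjustment")} is \code{TRUE} when
#'   any SMD meets the threshold.
#' @export
balance_report <- function(data, covariates, group = "arm",
                           threshold = 0.10) {
  g <- data[[group]]
  lv <- unique(g[!is.na(g)])
  stopifnot(length(lv) == 2)
  one <- function(v) {
    x <- data[[v]]
    if (is.numeric(x)) return(smd(x[g == lv[1]], x[g == lv[2]]))
    f <- factor(x)
    if (nlevels(f) <= 2)
      return(smd(f[g == lv[1]] == levels(f)[1],
                 f[g == lv[2]] == levels(f)[1], type = "binary"))
    max(vapply(levels(f), function(l)
      smd(f[g == lv[1]] == l, f[g == lv[2]] == l, type = "binary"),
      numeric(1)))
  }
  vals <- vapply(covariates, one, numeric(1))
  out <- data.frame(covariate = covariates, smd = unname(vals),
                    flagged = unname(vals) >= threshold)
  attr(out, "needs_adjustment") <- any(out$flagged)
  out
}

#' Greedy 1:1 nearest-neighbour matching on a score
#'
#' Treated units are processed in descending score order; each takes the
#' unused donor with the smallest absolute score difference (exact ties
#' broken by a seeded random draw). Without replacement: each donor is used
#' at most once. The result is invariant to affine increasing transforms of
#' the score.
#'
#' @param score_treated,score_donor Numeric scores.
#' @param seed Integer seed for tie-breaking.
#' @param caliper Optional maximum admissible score distance; treated units
#'   with no donor inside it raise an error (the per-protocol design
#'   requires every treated unit matched).
#' @return Data frame with \code{treated} and \code{donor} position indices
#'   and the score \code{distance}.
#' @export
nn_match <- function(score_treated, score_donor, seed = 1L, caliper = NULL) {
  nt <- length(score_treated); nd <- length(score_donor)
  if (nd < nt) stop("donor pool smaller than treated pool")
  set.seed(seed)
  ord <- order(score_treated, decreasing = TRUE)
  free <- rep(TRUE, nd)
  res <- matrix(NA_real_, nt, 2)
  for (i in ord) {
    d <- abs(score_donor - score_treated[i])
    d[!free] <- Inf
    best <- which(d == min(d))
    pick <- if (length(best) > 1L) best[sample.int(length(best), 1L)]
            else best
    if (!is.null(caliper) && d[pick] > caliper)
      stop("no donor within caliper for a treated unit")
    free[pick] <- FALSE
    res[i, ] <- c(pick, d[pick])
  }
  data.frame(treated = seq_len(nt), donor = res[, 1], distance = res[, 2])
}

#' Propensity-score matched control selection
#'
#' Fits a main-effects logistic regression of treated-status on the matching
#' covariates over the stacked treated and donor tables, then greedily
#' 1:1-matches on the linear predictor via \code{\link{nn_match}}. No caliper
#' by default. Returns equal-sized matched groups.
#'
#' @param treated,donors Data frames (disjoint units) holding the covariates.
#' @param covariates Character vector of covariate columns.
#' @param seed Tie-breaking seed.
#' @param caliper Optional caliper on the linear-predictor scale.
#' @return List with \code{pairs} (row indices into \code{treated} /
#'   \code{donors} plus distance), \code{ps_treated}, \code{ps_donor}
#'   (fitted propensities), and the fitted \code{model}.
#' @export
propensity_match <- function(treated, donors, covariates, seed = 1L,
                             caliper = NULL) {
  if (!nrow(treated)) stop("empty treated pool")
  stacked <- rbind(treated[covariates], donors[covariates])
  stacked$.treated <- rep(c(1L, 0L), c(nrow(treated), nrow(donors)))
  fml <- stats::reformulate(covariates, ".treated")
  fit <- stats::glm(fml, data = stacked, family = stats::binomial())
  if (!fit$converged) stop("propensity model did not converge")
  lp <- stats::predict(fit, type = "link")
  lp_t <- lp[seq_len(nrow(treated))]
  lp_d <- lp[-seq_len(nrow(treated))]
  pairs <- nn_match(lp_t, lp_d, seed = seed, caliper = caliper)
  list(pairs = pairs, ps_treated = stats::plogis(lp_t),
       ps_donor = stats::plogis(lp_d), model = fit)
}
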