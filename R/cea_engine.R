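# Incremental cost-effectiveness inference: point estimates, ICER and
# dominance classification, stratified bootstrap clouds, percentile
# confidence intervals, confidence ellipses and acceptability curves.
# All arithmetic is carried at full precision; rounding happens only at
# report time.

effect_kinds <- function() c("qaly", "dcdl", "whodas")

# incremental effect in natural units, oriented so that positive favours the
# intervention: QALY gains directly, deterioration probability and WHODAS
# score inverted because lower is better there
delta_effect_natural <- function(mean_eff_ig, mean_eff_cg, effect_kind) {
  switch(effect_kind,
         qaly = mean_eff_ig - mean_eff_cg,
         dcdl = mean_eff_cg - mean_eff_ig,
         whodas = mean_eff_cg - mean_eff_ig)
}

#' Incremental costs, effects and cost-effectiveness verdict
#'
#' Incremental cost is the mean difference IG - CG. The incremental effect
#' is the mean difference for the QALY, and the inverted difference (CG -
#' IG) for deterioration in care dependency (reported in percentage points;
#' the absolute risk reduction) and for the WHODAS 2.0 score, because lower
#' values are preferable there. The verdict follows the cost-effectiveness
#' plane quadrant: more effective and more costly yields an ICER
#' (incremental cost / incremental effect, in natural units, i.e. EUR per
#' whole prevented deterioration); more effective and less costly means the
#' intervention dominates; less effective and more costly means the control
#' dominates; less effective and less costly yields the south-west-quadrant
#' ICER with an explicit quadrant label. A zero incremental effect with
#' non-zero incremental cost is reported as an undefined ICER, not an error.
#'
#' @param costs_ig,costs_cg Per-patient total costs (EUR).
#' @param effects_ig,effects_cg Per-patient effects: QALYs, 0/1 deterioration
#'   indicators, or WHODAS scores.
#' @param effect_kind One of "qaly", "dcdl", "whodas".
#' @return Object of class \code{"incremental_result"}: means and SDs per
#'   arm, \code{delta_cost}, \code{delta_effect} (percentage points for
#'   dcdl), \code{delta_effect_natural}, \code{icer}, \code{verdict},
#'   \code{quadrant}.
#' @export
incremental <- function(costs_ig, costs_cg, effects_ig, effects_cg,
                        effect_kind = c("qaly", "dcdl", "whodas")) {
  effect_kind <- match.arg(effect_kind)
  stopifnot(length(costs_ig) > 0, length(costs_cg) > 0)
  effects_ig <- as.numeric(effects_ig); effects_cg <- as.numeric(effects_cg)
  dc <- mean(costs_ig) - mean(costs_cg)
  de <- delta_effect_natural(mean(effects_ig), mean(effects_cg), effect_kind)
  quadrant <- paste0(if (de >= 0) "E" else "W", if (dc >= 0) "N" else "S")
  quadrant <- c(EN = "north-east", ES = "south-east",
                WN = "north-west", WS = "south-west")[[quadrant]]
  if (de > 0 && dc < 0) {
    verdict <- "intervention_dominates"; icer <- NA_real_
  } else if (de < 0 && dc > 0) {
    verdict <- "control_dominates"; icer <- NA_real_
  } else if (de == 0) {
    verdict <- "undefined_icer"; icer <- NA_real_
  } else {
    verdict <- "icer"; icer <- dc / de
  }
  structure(list(
    effect_kind = effect_kind,
    n_ig = length(costs_ig), n_cg = length(costs_cg),
    mean_cost_ig = mean(costs_ig), sd_cost_ig = stats::sd(costs_ig),
    mean_cost_cg = mean(costs_cg), sd_cost_cg = stats::sd(costs_cg),
    mean_effect_ig = mean(effects_ig), sd_effect_ig = stats::sd(effects_ig),
    mean_effect_cg = mean(effects_cg), sd_effect_cg = stats::sd(effects_cg),
    delta_cost = dc,
    delta_effect = if (effect_kind == "dcdl") 100 * de else de,
    delta_effect_natural = de,
    icer = icer, verdict = verdict, quadrant = quadrant),
    class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("Incremental result (%s): dC = %.2f EUR, dE = %.4f%s\n",
              x$effect_kind, x$delta_cost, x$delta_effect,
              if (x$effect_kind == "dcdl") " pp" else ""))
  cat(sprintf("  verdict: %s%s (quadrant %s)\n", x$verdict,
              if (x$verdict == "icer") sprintf(", ICER = %.1f", x$icer)
              else "", x$quadrant))
  invisible(x)
}

#' Stratified bootstrap cloud of incremental costs and effects
#'
#' Per replicate, patients are resampled with replacement within arm (arm
#' sizes preserved, matching the two-sample design) and the incremental
#' statistic pipeline is recomputed. Deterministic given the seed.
#'
#' @param cost,effect Per-patient totals and effects.
#' @param arm "IG"/"CG" per patient.
#' @param effect_kind One of "qaly", "dcdl", "whodas".
#' @param B Number of resamples (default 10,000).
#' @param seed Integer seed.
#' @return Object of class \code{"bootstrap_cloud"}: vectors
#'   \code{delta_cost}, \code{delta_effect} (natural units), the point
#'   estimate, \code{B} and \code{seed}.
#' @export
bootstrap_cloud <- function(cost, effect, arm,
                            effect_kind = c("qaly", "dcdl", "whodas"),
                            B = 10000L, seed = 1L) {
  effect_kind <- match.arg(effect_kind)
  if (B < 2) stop("B must be at least 2")
  ig <- arm == "IG"
  ci <- cost[ig]; cc <- cost[!ig]
  ei <- as.numeric(effect[ig]); ec <- as.numeric(effect[!ig])
  n_i <- length(ci); n_c <- length(cc)
  set.seed(seed)
  dc <- de <- numeric(B)
  chunk <- max(1L, min(B, floor(2e7 / max(n_i + n_c, 1L))))
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    idx_i <- matrix(sample.int(n_i, n_i * b, replace = TRUE), n_i, b)
    idx_c <- matrix(sample.int(n_c, n_c * b, replace = TRUE), n_c, b)
    mci <- colMeans(matrix(ci[idx_i], n_i, b))
    mcc <- colMeans(matrix(cc[idx_c], n_c, b))
    mei <- colMeans(matrix(ei[idx_i], n_i, b))
    mec <- colMeans(matrix(ec[idx_c], n_c, b))
    sel <- done + seq_len(b)
    dc[sel] <- mci - mcc
    de[sel] <- delta_effect_natural(mei, mec, effect_kind)
    done <- done + b
  }
  structure(list(delta_cost = dc, delta_effect = de,
                 effect_kind = effect_kind, B = as.integer(B),
                 seed = as.integer(seed),
                 point = incremental(ci, cc, ei, ec, effect_kind)),
            class = "bootstrap_cloud")
}

#' Percentile confidence interval from a bootstrap cloud
#'
#' Endpoints are order statistics of the replicates under the inverse-ECDF
#' convention (\code{stats::quantile} type 1): the \code{ceiling(B * p)}-th
#' sorted value at probability \code{p}.
#'
#' @param x Numeric vector of replicates.
#' @param level Confidence level (default 0.95).
#' @return Length-2 numeric vector (lower, upper).
#' @export
percentile_ci <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  unname(stats::quantile(x, c(a, 1 - a), type = 1, names = FALSE))
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay threshold lambda the acceptability is the
#' fraction of bootstrap replicates with strictly positive net monetary
#' benefit, \code{lambda * dE - dC > 0}, with the incremental effect in
#' natural units (a whole prevented deterioration, not a percentage point),
#' so lambda is EUR per QALY, per prevented deterioration, or per WHODAS
#' point. At lambda = 0 this reduces to the probability of cost savings.
#'
#' @param cloud A \code{\link{bootstrap_cloud}}.
#' @param wtp_grid Non-negative thresholds in EUR (default 0 to 100,000 in
#'   steps of 1,000).
#' @return Data frame of class \code{"ceac"} with columns \code{wtp},
#'   \code{probability}.
#' @export
ceac <- function(cloud, wtp_grid = seq(0, 100000, by = 1000)) {
  stopifnot(inherits(cloud, "bootstrap_cloud"), length(cloud$delta_cost) > 0)
  if (any(wtp_grid < 0)) stop("willingness-to-pay must be non-negative")
  prob <- vapply(wtp_grid, function(l)
    mean(l * cloud$delta_effect - cloud$delta_cost > 0), numeric(1))
  structure(data.frame(wtp = wtp_grid, probability = prob),
            class = c("ceac", "data.frame"))
}

#' Cost-effectiveness plane summary with confidence ellipse
#'
#' The ellipse is the bivariate-normal contour with the mean vector and
#' covariance of the cloud, scaled by the chi-square (2 df) quantile at the
#' confidence level. Quadrant shares and axis crossings (whether the ellipse
#' spans both signs of an axis) are reported; a collinear cloud is flagged
#' degenerate.
#'
#' @param cloud A \code{\link{bootstrap_cloud}}.
#' @param confidence Contour level (default 0.95).
#' @param n_points Points on the ellipse outline.
#' @return List of class \code{"ce_plane"}: \code{center}, \code{cov},
#'   \code{ellipse} (outline, columns effect/cost), \code{quadrant_shares},
#'   \code{crosses_effect_axis}, \code{crosses_cost_axis},
#'   \code{degenerate}.
#' @export
ce_plane <- function(cloud, confidence = 0.95, n_points = 181L) {
  stopifnot(inherits(cloud, "bootstrap_cloud"),
            length(cloud$delta_cost) >= 3)
  xy <- cbind(effect = cloud$delta_effect, cost = cloud$delta_cost)
  ctr <- colMeans(xy)
  S <- stats::cov(xy)
  degenerate <- det(S) < .Machine$double.eps * max(diag(S), 1)^2
  ell <- NULL
  if (!degenerate) {
    r <- sqrt(stats::qchisq(confidence, df = 2))
    theta <- seq(0, 2 * pi, length.out = n_points)
    circ <- rbind(cos(theta), sin(theta))
    ell <- t(ctr + r * t(chol(S)) %*% circ)
    colnames(ell) <- c("effect", "cost")
  }
  qs <- c(
    NE = mean(xy[, 1] > 0 & xy[, 2] > 0),
    SE = mean(xy[, 1] > 0 & xy[, 2] <= 0),
    NW = mean(xy[, 1] <= 0 & xy[, 2] > 0),
    SW = mean(xy[, 1] <= 0 & xy[, 2] <= 0))
  structure(list(center = ctr, cov = S, confidence = confidence,
                 ellipse = ell, quadrant_shares = qs,
                 crosses_effect_axis = !degenerate &&
                   min(ell[, 1]) < 0 && max(ell[, 1]) > 0,
                 crosses_cost_axis = !degenerate &&
                   min(ell[, 2]) < 0 && max(ell[, 2]) > 0,
                 degenerate = degenerate),
            class = "ce_plane")
}
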