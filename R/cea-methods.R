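# Methods for the "cea" fit.

effect_unit <- function(effect_kind, natural = FALSE) {
  switch(effect_kind,
         qaly = "QALY",
         dcdl = if (natural) "prevented deterioration"
                else "percentage points prevented deterioration",
         whodas = "WHODAS 2.0 points gained")
}

#' @export
print.cea <- function(x, ...) {
  p <- x$point
  cat(sprintf("Cost-effectiveness analysis: %s, effect = %s%s\n",
              x$variant, x$effect_kind,
              if (!is.null(x$subgroup)) paste0(", subgroup = ", x$subgroup)
              else ""))
  if (x$matched)
    cat("  propensity-score matched population",
        "(non-randomised, exploratory)\n")
  cat(sprintf("  N: %d IG / %d CG\n", x$n_ig, x$n_cg))
  cat(sprintf("  Incremental costs: %s EUR (95%% CI %s; %s)\n",
              format(round_half_up(p$delta_cost), big.mark = ","),
              format(round_half_up(x$ci_cost[1]), big.mark = ","),
              format(round_half_up(x$ci_cost[2]), big.mark = ",")))
  cat(sprintf("  Incremental effects: %s %s (95%% CI %s; %s)\n",
              round_half_up(p$delta_effect, 2), effect_unit(x$effect_kind),
              round_half_up(x$ci_effect[1], 2),
              round_half_up(x$ci_effect[2], 2)))
  cat("  ", switch(p$verdict,
    icer = sprintf("ICER: %s EUR per %s%s",
                   format(round_half_up(p$icer), big.mark = ","),
                   effect_unit(x$effect_kind, natural = TRUE),
                   if (p$quadrant == "south-west")
                     " (south-west quadrant)" else ""),
    intervention_dominates = "Intervention dominates (more effective, less costly)",
    control_dominates = "Control dominates (intervention less effective, more costly)",
    undefined_icer = "ICER undefined (zero incremental effect)"), "\n",
    sep = "")
  invisible(x)
}

#' @export
summary.cea <- function(object, ...) {
  x <- object
  p <- x$point
  print(x)
  cat(sprintf("\n  Mean (SD) costs: IG %s (%s), CG %s (%s) EUR\n",
              format(round_half_up(p$mean_cost_ig), big.mark = ","),
              format(round_half_up(p$sd_cost_ig), big.mark = ","),
              format(round_half_up(p$mean_cost_cg), big.mark = ","),
              format(round_half_up(p$sd_cost_cg), big.mark = ",")))
  if (x$effect_kind == "dcdl")
    cat(sprintf("  Deterioration: IG %d/%d (%.2f%%), CG %d/%d (%.2f%%)\n",
                round(p$mean_effect_ig * x$n_ig), x$n_ig,
                100 * p$mean_effect_ig,
                round(p$mean_effect_cg * x$n_cg), x$n_cg,
                100 * p$mean_effect_cg))
  else
    cat(sprintf("  Mean (SD) effects: IG %.2f (%.2f), CG %.2f (%.2f)\n",
                p$mean_effect_ig, p$sd_effect_ig,
                p$mean_effect_cg, p$sd_effect_cg))
  for (l in c(0, 50000, 100000)) {
    i <- which(x$ceac$wtp == l)
    if (length(i))
      cat(sprintf("  P(cost-effective) at %s EUR: %.0f%%\n",
                  format(l, big.mark = ","), 100 * x$ceac$probability[i]))
  }
  qs <- x$plane$quadrant_shares
  cat(sprintf("  Cloud quadrant shares: NE %.2f, SE %.2f, NW %.2f, SW %.2f\n",
              qs["NE"], qs["SE"], qs["NW"], qs["SW"]))
  cat(sprintf("  95%% ellipse crosses effect axis: %s; cost axis: %s\n",
              x$plane$crosses_effect_axis, x$plane$crosses_cost_axis))
  if (!is.null(x$rubin))
    cat(sprintf(paste0("  Rubin-pooled comparison: dC %s EUR ",
                       "(95%% CI %s; %s), dE %.4f (95%% CI %.4f; %.4f)\n"),
                format(round_half_up(x$rubin$cost$estimate),
                       big.mark = ","),
                format(round_half_up(x$rubin$cost$ci[1]), big.mark = ","),
                format(round_half_up(x$rubin$cost$ci[2]), big.mark = ","),
                x$rubin$effect$estimate, x$rubin$effect$ci[1],
                x$rubin$effect$ci[2]))
  invisible(x)
}

#' @export
coef.cea <- function(object, ...) {
  p <- object$point
  c(delta_cost = p$delta_cost, delta_effect = p$delta_effect,
    icer = p$icer)
}

#' @export
confint.cea <- function(object, parm, level = 0.95, ...) {
  if (level != object$manifest$conf) {
    ci_c <- percentile_ci(object$cloud$delta_cost, level)
    ci_e <- percentile_ci(object$cloud$delta_effect, level)
    if (object$effect_kind == "dcdl") ci_e <- 100 * ci_e
  } else {
    ci_c <- object$ci_cost; ci_e <- object$ci_effect
  }
  out <- rbind(delta_cost = ci_c, delta_effect = ci_e)
  colnames(out) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                          " %")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Plot a cost-effectiveness fit
#'
#' \code{type = "plane"} draws the bootstrap cloud on the incremental
#' cost-effectiveness plane with the point estimate and the confidence
#' ellipse; \code{type = "ceac"} draws the acceptability curve.
#'
#' @param x A \code{\link{cea}} fit.
#' @param type "plane" or "ceac".
#' @param max_points Cloud points drawn at most (thinned deterministically).
#' @param ... Passed to the underlying plot call.
#' @export
plot.cea <- function(x, type = c("plane", "ceac"), max_points = 2000L,
                     ...) {
  type <- match.arg(type)
  if (type == "ceac") {
    graphics::plot(x$ceac$wtp, x$ceac$probability, type = "l", lwd = 2,
                   ylim = c(0, 1),
                   xlab = "Willingness to pay (EUR)",
                   ylab = "Probability cost-effective",
                   main = sprintf("CEAC (%s, %s)", x$variant,
                                  x$effect_kind), ...)
    graphics::abline(v = 50000, lty = 3)
    return(invisible(x))
  }
  de <- x$cloud$delta_effect
  dc <- x$cloud$delta_cost
  if (x$effect_kind == "dcdl") de <- 100 * de
  thin <- if (length(de) > max_points)
    seq(1L, length(de), length.out = max_points) else seq_along(de)
  graphics::plot(de[thin], dc[thin], pch = 16, cex = 0.3,
                 col = grDevices::adjustcolor("pink3", 0.6),
                 xlab = sprintf("Incremental effect (%s)",
                                effect_unit(x$effect_kind)),
                 ylab = "Incremental cost (EUR)",
                 main = sprintf("CE plane (%s, %s)", x$variant,
                                x$effect_kind), ...)
  graphics::abline(h = 0, v = 0, col = "grey40")
  if (!x$plane$degenerate) {
    ell <- x$plane$ellipse
    ex <- ell[, "effect"]
    if (x$effect_kind == "dcdl") ex <- 100 * ex
    graphics::lines(ex, ell[, "cost"], col = "red", lwd = 2)
  }
  pe <- x$point$delta_effect
  graphics::points(pe, x$point$delta_cost, col = "red", pch = 19)
  invisible(x)
}
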