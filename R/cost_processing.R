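# Winsorisation of skewed cost blocks and assembly of analysis-ready totals.

#' Winsorise one cost block
#'
#' Values above the empirical percentile threshold are replaced by the
#' threshold; values at or below it, and missing entries, are untouched.
#' The threshold uses the linear-interpolation quantile convention
#' (\code{stats::quantile} type 7), computed pooled across both arms, and
#' missing entries are ignored when computing it. The default percentile is
#' 0.975: only extreme outliers that would dominate arm means are capped.
#' Intervention costs are never winsorised (enforced by the caller).
#'
#' @param values Numeric vector (may contain \code{NA}).
#' @param percentile Fraction in (0, 1); default 0.975.
#' @return Winsorised vector of the same length.
#' @export
winsorise_block <- function(values, percentile = 0.975) {
  if (!length(values) || all(is.na(values))) stop("empty cost block")
  stopifnot(percentile > 0, percentile < 1)
  thr <- stats::quantile(values, percentile, na.rm = TRUE, names = FALSE,
                         type = 7)
  values[!is.na(values) & values > thr] <- thr
  values
}

#' Assemble per-patient total costs
#'
#' Total cost per patient is intervention + index stay + sum of all follow-up
#' components. With \code{winsorised = TRUE} the index-stay column and every
#' follow-up component column are winsorised (pooled across arms) before
#' summation; the intervention column never is. With \code{winsorised =
#' FALSE} raw components are summed (the no-winsorisation sensitivity
#' analysis). \code{NA} components propagate into the total, marking the
#' patient for imputation.
#'
#' @param intervention Numeric vector of intervention costs.
#' @param index_cost Numeric vector of index-stay costs.
#' @param followup Numeric matrix of follow-up components (one column per
#'   category-visit component).
#' @param winsorised Logical flag.
#' @param percentile Winsorisation percentile.
#' @return List with \code{index_cost}, \code{followup} (processed
#'   components) and \code{total}.
#' @export
assemble_totals <- function(intervention, index_cost, followup,
                            winsorised = TRUE, percentile = 0.975) {
  followup <- as.matrix(followup)
  if (winsorised) {
    index_cost <- winsorise_block(index_cost, percentile)
    followup <- apply(followup, 2, winsorise_block, percentile = percentile)
  }
  list(index_cost = index_cost, followup = followup,
       total = intervention + index_cost + rowSums(followup))
}
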