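# Per-patient effect measures: QALY from quarterly EQ-5D-5L utilities,
# deterioration in care dependency level (DCDL), WHODAS 2.0 simple score.
# All three carry a worst-score-at-death rule.

#' Quality-adjusted life year over the postoperative year
#'
#' The QALY is the arithmetic mean of the four quarterly utilities (months 3,
#' 6, 9, 12 after surgery). Utility is set to 0 at every assessment point on
#' or after the date of death; there is no partial-quarter proration, since
#' the construction averages four discrete assessments. If any non-death slot
#' is missing the QALY is missing (to be resolved upstream by imputation).
#' Baseline utility is not part of the QALY.
#'
#' @param utilities Numeric vector of length 4 (3/6/9/12-month utilities),
#'   values in [-0.661, 1] or \code{NA}.
#' @param death_day Day of death relative to surgery, or \code{NA} if alive.
#' @return QALY in [-0.661, 1], or \code{NA}.
#' @export
compute_qaly <- function(utilities, death_day = NA) {
  stopifnot(length(utilities) == 4L)
  if (any(utilities < -0.661 - 1e-9 | utilities > 1 + 1e-9, na.rm = TRUE))
    stop("utility outside [-0.661, 1]")
  if (!is.na(death_day))
    utilities[visit_days() >= death_day] <- 0
  if (anyNA(utilities)) return(NA_real_)
  mean(utilities)
}

#' Deterioration in care dependency level (DCDL)
#'
#' Care dependency is graded 0 (none) to 5 (highest). The change from
#' baseline to 12 months is dichotomised: deterioration iff the 12-month
#' level strictly exceeds baseline. Death sets the 12-month level to 5 and
#' counts as deterioration automatically, regardless of baseline (a patient
#' dying from baseline level 5 therefore still counts as deteriorated; the
#' trial contained a single such baseline patient and the convention follows
#' the death rule, not the strict-increase rule).
#'
#' @param level_baseline,level_12m Integer levels 0--5 (\code{level_12m} may
#'   be \code{NA}).
#' @param died Logical.
#' @return \code{TRUE} (deteriorated), \code{FALSE}, or \code{NA}.
#' @export
compute_dcdl <- function(level_baseline, level_12m = NA, died = FALSE) {
  chk <- c(level_baseline, level_12m[!is.na(level_12m)])
  if (any(chk < 0 | chk > 5)) stop("care dependency level outside 0..5")
  n <- max(length(level_baseline), length(level_12m), length(died))
  level_baseline <- rep_len(level_baseline, n)
  level_12m <- rep_len(level_12m, n)
  died <- rep_len(died, n)
  out <- level_12m > level_baseline
  out[died] <- TRUE
  out
}

#' WHODAS 2.0 12-item simple score
#'
#' Sum of the 12 items (each 1--5), ranging from 12 (best) to 60 (worst).
#' Death sets the score to 60.
#'
#' @param items Numeric vector of 12 items in 1--5 (ignored when
#'   \code{died}).
#' @param died Logical scalar.
#' @return Score in 12--60, or \code{NA} when items are missing.
#' @export
compute_whodas <- function(items, died = FALSE) {
  if (isTRUE(died)) return(60)
  if (length(items) != 12L) stop("WHODAS 2.0 requires exactly 12 items")
  if (any(items < 1 | items > 5, na.rm = TRUE))
    stop("WHODAS item outside 1..5")
  if (anyNA(items)) return(NA_real_)
  sum(items)
}
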