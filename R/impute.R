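# Chained-equations multiple imputation with predictive-mean-matching draws,
# and individual-level combination of the imputed datasets.
#
# Cells determined by the worst-score-at-death rules (post-death zero costs
# and utilities, level-5 care dependency, WHODAS 60) are filled before
# imputation and are never treated as missing.

#' Imputation settings
#'
#' @param m Number of imputed datasets (>= 2). Default 20.
#' @param iterations Chained-equation sweeps per dataset. Default 10.
#' @param donors Predictive-mean-matching donor-pool size. Default 5: each
#'   missing cell receives the observed value of one of the 5 observed rows
#'   whose model prediction is closest, which respects zero-inflated cost
#'   supports and ordinal scales (pure regression draws would produce
#'   negative costs).
#' @param seed Integer seed; imputation is deterministic given it.
#' @return Object of class \code{"impute_spec"}.
#' @export
impute_spec <- function(m = 20L, iterations = 10L, donors = 5L, seed = 1L) {
  stopifnot(m >= 2, iterations >= 1, donors >= 1)
  structure(list(m = as.integer(m), iterations = as.integer(iterations),
                 donors = as.integer(donors), seed = as.integer(seed)),
            class = "impute_spec")
}

# one Bayesian PMM draw for variable y given complete predictor matrix X
# (type-1 matching: predictions for observed rows from the least-squares fit,
# for missing rows from a posterior draw of the coefficients)
pmm_draw <- function(y, X, mis, donors) {
  obs <- !mis
  yo <- y[obs]
  if (sum(obs) < ncol(X) + 2L || stats::var(yo) == 0)
    return(sample(yo, sum(mis), replace = TRUE))
  qrX <- qr(X[obs, , drop = FALSE])
  keep <- qrX$pivot[seq_len(qrX$rank)]
  Xo <- X[obs, keep, drop = FALSE]
  Xm <- X[mis, keep, drop = FALSE]
  fit <- stats::lm.fit(Xo, yo)
  df <- max(1L, length(yo) - fit$rank)
  s2 <- sum(fit$residuals^2) / df
  s2_star <- s2 * df / stats::rchisq(1, df)
  R <- qr.R(fit$qr)[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
  beta <- fit$coefficients[seq_len(fit$rank)]
  beta_star <- beta + sqrt(s2_star) *
    backsolve(R, stats::rnorm(fit$rank))
  cols <- fit$qr$pivot[seq_len(fit$rank)]
  yhat_obs <- drop(Xo[, cols, drop = FALSE] %*% beta)
  yhat_mis <- drop(Xm[, cols, drop = FALSE] %*% beta_star)
  k <- min(donors, length(yo))
  vapply(yhat_mis, function(p) {
    d <- abs(yhat_obs - p)
    pool <- order(d)[seq_len(k)]
    yo[pool[sample.int(k, 1L)]]
  }, numeric(1))
}

# design matrix (intercept + numeric-coded columns) from named columns
design_matrix <- function(data, cols) {
  num <- lapply(cols, function(cl) {
    v <- data[[cl]]
    if (is.character(v) || is.factor(v)) {
      f <- factor(v)
      if (nlevels(f) < 2L) return(NULL)
      m <- stats::model.matrix(~ f)[, -1, drop = FALSE]
      colnames(m) <- paste0(cl, seq_len(ncol(m)))
      m
    } else if (is.logical(v)) matrix(as.numeric(v), ncol = 1,
                                     dimnames = list(NULL, cl))
    else matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, cl))
  })
  cbind(`(Intercept)` = 1, do.call(cbind, num))
}

#' Chained-equations multiple imputation
#'
#' Produces \code{m} completed copies of \code{data}. Per sweep, each
#' variable with missing entries is re-imputed from a linear model on its
#' predictor set (refit each sweep on the current completed data) with
#' predictive-mean-matching draws. Variables are initialised by sampling
#' their observed values. Deterministic given \code{spec$seed}.
#'
#' @param data Data frame; only columns named in \code{predictor_sets} are
#'   touched.
#' @param predictor_sets Named list: for each variable to impute, the
#'   character vector of its predictor columns (which must be complete or
#'   themselves imputed variables).
#' @param spec An \code{\link{impute_spec}}.
#' @return List of \code{m} completed data frames; the original missingness
#'   pattern is in \code{attr(, "missing_pattern")}.
#' @export
impute_dataset <- function(data, predictor_sets, spec = impute_spec()) {
  stopifnot(inherits(spec, "impute_spec"))
  vars <- names(predictor_sets)
  mis_pat <- lapply(stats::setNames(vars, vars),
                    function(v) is.na(data[[v]]))
  vars <- vars[vapply(mis_pat, any, TRUE)]
  for (v in vars)
    if (all(mis_pat[[v]])) stop("variable with zero observed values: ", v)
  if (!length(vars)) {
    out <- rep(list(data), spec$m)
    attr(out, "missing_pattern") <- mis_pat
    return(out)
  }
  set.seed(spec$seed)
  out <- vector("list", spec$m)
  for (chain in seq_len(spec$m)) {
    cur <- data
    for (v in vars) {
      mis <- mis_pat[[v]]
      cur[[v]][mis] <- sample(data[[v]][!mis], sum(mis), replace = TRUE)
    }
    for (it in seq_len(spec$iterations)) {
      for (v in vars) {
        mis <- mis_pat[[v]]
        X <- design_matrix(cur, predictor_sets[[v]])
        cur[[v]][mis] <- pmm_draw(cur[[v]], X, mis, spec$donors)
      }
    }
    out[[chain]] <- cur
  }
  attr(out, "missing_pattern") <- mis_pat
  out
}

#' Combine imputed datasets at the individual level
#'
#' Collapses the \code{m} completed datasets to a single analysis dataset
#' before any statistic is computed: per originally-missing cell, continuous
#' variables take the mean across imputations and ordinal variables the mode
#' (ties broken toward the worse, i.e. higher, health state). Observed cells
#' pass through unchanged. Totals and aggregated outcomes must be recomputed
#' from the combined component-level data afterwards. Combining before
#' analysis understates between-imputation variance, so reported uncertainty
#' is a lower bound; see \code{\link{pool_rubin}} for the conventional
#' alternative.
#'
#' @param imputations Output of \code{\link{impute_dataset}}.
#' @param ordinal Character vector of column names combined by worse-ties
#'   mode rather than mean.
#' @return One combined data frame.
#' @export
combine_individual <- function(imputations, ordinal = character()) {
  m <- length(imputations)
  stopifnot(m >= 1)
  out <- imputations[[1]]
  if (m == 1L) return(out)
  mis_pat <- attr(imputations, "missing_pattern")
  for (v in names(mis_pat)) {
    mis <- mis_pat[[v]]
    if (!any(mis)) next
    cells <- sapply(imputations, function(d) d[[v]][mis])  # n_mis x m
    cells <- matrix(cells, ncol = m)
    if (v %in% ordinal) {
      out[[v]][mis] <- apply(cells, 1, function(r) {
        tab <- table(r)
        worst <- max(as.numeric(names(tab)[tab == max(tab)]))
        worst
      })
    } else {
      out[[v]][mis] <- rowMeans(cells)
    }
  }
  out
}

#' Rubin's-rules pooling of per-dataset estimates
#'
#' Conventional alternative to individual-level combination: analyse each
#' imputed dataset, then pool. Total variance is the within-imputation
#' variance plus (1 + 1/m) times the between-imputation variance;
#' Barnard-Rubin small-sample degrees of freedom.
#'
#' @param estimates Numeric vector of per-dataset point estimates.
#' @param variances Numeric vector of per-dataset squared standard errors.
#' @param level Confidence level. Default 0.95.
#' @param n_obs Complete-data sample size for the degrees-of-freedom
#'   correction (Inf for the large-sample form).
#' @return List with \code{estimate}, \code{se}, \code{ci}, \code{df}.
#' @export
pool_rubin <- function(estimates, variances, level = 0.95, n_obs = Inf) {
  m <- length(estimates)
  stopifnot(m >= 2, length(variances) == m)
  qbar <- mean(estimates)
  w <- mean(variances)
  b <- stats::var(estimates)
  t_var <- w + (1 + 1 / m) * b
  r <- (1 + 1 / m) * b / w
  df_old <- (m - 1) * (1 + 1 / r)^2
  df <- df_old
  if (is.finite(n_obs)) {
    lambda <- (1 + 1 / m) * b / t_var
    df_com <- n_obs - 1
    df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
    df <- 1 / (1 / df_old + 1 / df_obs)
  }
  alpha <- 1 - level
  half <- stats::qt(1 - alpha / 2, df) * sqrt(t_var)
  list(estimate = qbar, se = sqrt(t_var),
       ci = c(qbar - half, qbar + half), df = df)
}
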