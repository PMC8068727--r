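#' Fit indices from chi-square summaries
#'
#' Pure-function core of the fit-index block: CFI, TLI, RMSEA with a 90%
#' confidence interval obtained by inverting the noncentral chi-square
#' distribution. With `df = 0` RMSEA and TLI are undefined and returned as
#' `NA` (never NaN propagation).
#'
#' * `CFI = 1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, 0)`
#' * `TLI = ((chi2_b/df_b) - (chi2/df)) / ((chi2_b/df_b) - 1)`
#' * `RMSEA = sqrt(max(chi2 - df, 0) / (df (n - 1)))`
#'
#' @param chi2,df Model chi-square and degrees of freedom.
#' @param baseline_chi2,baseline_df Independence-model chi-square and df on
#'   the same data.
#' @param n_obs Total number of observations.
#' @param conf_level Confidence level of the RMSEA interval.
#' @return A one-row tibble: cfi, tli, rmsea, rmsea_lower, rmsea_upper.
#' @export
#' @examples
#' fit_index_block(70.37, 9, 3000, 15, 3002)
fit_index_block <- function(chi2, df, baseline_chi2, baseline_df, n_obs,
                            conf_level = 0.90) {
  d <- max(chi2 - df, 0)
  db <- max(baseline_chi2 - baseline_df, 0)
  cfi <- if (max(db, d) == 0) 1 else 1 - d / max(db, d)
  tli <- if (df == 0 || baseline_df == 0) {
    NA_real_
  } else {
    num <- baseline_chi2 / baseline_df - chi2 / df
    den <- baseline_chi2 / baseline_df - 1
    if (den <= 0) NA_real_ else min(num / den, 1)
  }
  if (df == 0) {
    rmsea <- lo <- hi <- NA_real_
  } else {
    rmsea <- sqrt(d / (df * (n_obs - 1)))
    a <- (1 - conf_level) / 2
    lo_ncp <- invert_ncp(chi2, df, 1 - a)
    hi_ncp <- invert_ncp(chi2, df, a)
    lo <- sqrt(lo_ncp / (df * (n_obs - 1)))
    hi <- sqrt(hi_ncp / (df * (n_obs - 1)))
  }
  tibble::tibble(cfi = cfi, tli = tli, rmsea = rmsea,
                 rmsea_lower = lo, rmsea_upper = hi)
}

# largest ncp with pchisq(x, df, ncp) >= target (0 when none)
invert_ncp <- function(x, df, target) {
  if (pchisq(x, df, ncp = 0) < target) return(0)
  f <- function(l) pchisq(x, df, ncp = l) - target
  upper <- max(x, 1)
  while (f(upper) > 0) upper <- upper * 2
  uniroot(f, c(0, upper), tol = 1e-12)$root
}

#' Fit indices for a fitted model
#'
#' Populates CFI/TLI/RMSEA (via [fit_index_block()]), SRMR (root mean
#' square of the standardized residual covariances, pooled across groups)
#' and AIC (`-2 loglik + 2 npar`). Under a robust estimator the chi-squares
#' entering CFI/TLI/RMSEA are the mean-scaled ones.
#'
#' @param fit A `sem_fit`.
#' @param baseline Optional `sem_fit` of the independence model on the same
#'   data; defaults to the baseline stored by [fit_cfa()].
#' @return A one-row tibble of indices.
#' @export
fit_indices <- function(fit, baseline = NULL) {
  if (!inherits(fit, "sem_fit")) abort("`fit` must be a sem_fit")
  if (is.null(baseline)) {
    b <- fit$baseline
    if (is.null(b)) abort("no baseline model available")
  } else {
    b <- list(chi2 = baseline$chi2, df = baseline$df,
              chi2_scaled = baseline$chi2_scaled, loglik = baseline$loglik)
  }
  use_scaled <- fit$estimator == "ml_robust" && is.finite(fit$chi2_scaled %||%
                                                            NA_real_)
  chi2 <- if (use_scaled) fit$chi2_scaled else fit$chi2
  chi2_b <- if (use_scaled && is.finite(b$chi2_scaled %||% NA_real_)) {
    b$chi2_scaled
  } else {
    b$chi2
  }
  blk <- fit_index_block(chi2, fit$df, chi2_b, b$df, fit$n_total)
  # SRMR on the correlation metric, pooled over groups
  resid2 <- unlist(lapply(seq_along(fit$stats), function(gi) {
    s <- fit$stats[[gi]]$S
    if (is.null(s)) return(NULL)
    sig <- fit$implied[[gi]]$sigma
    d <- sqrt(diag(s))
    r <- (s - sig) / outer(d, d)
    vech(r)^2
  }))
  srmr <- if (length(resid2)) sqrt(mean(resid2)) else NA_real_
  dplyr::mutate(
    blk,
    srmr = srmr,
    aic = -2 * fit$loglik + 2 * fit$npar,
    chi2 = chi2, df = fit$df, n_obs = fit$n_total
  )
}

#' Compare two nested factor models with delta-fit criteria
#'
#' Large-sample chi-square difference tests reject trivial restrictions, so
#' model comparison uses changes in fit indices instead: the restricted
#' model is judged `"depreciated"` when CFI drops by more than `delta_cfi`
#' (default 0.01) or RMSEA rises by more than `delta_rmsea` (default
#' 0.015); otherwise `"equivalent"`. Delta chi-square, df and AIC are
#' reported alongside.
#'
#' @param free The less constrained `sem_fit`.
#' @param restricted The nested, more constrained `sem_fit` on the same
#'   data (equal total n; df must not be smaller than the free model's).
#' @param delta_cfi,delta_rmsea Depreciation thresholds.
#' @return A `comparison_verdict` (tibble row + verdict).
#' @export
compare_models <- function(free, restricted, delta_cfi = 0.01,
                           delta_rmsea = 0.015) {
  if (!inherits(free, "sem_fit") || !inherits(restricted, "sem_fit")) {
    abort("both arguments must be sem_fit objects")
  }
  if (free$n_total != restricted$n_total) {
    abort("models were fitted to different data (unequal n)")
  }
  if (restricted$df < free$df) {
    abort("`restricted` has fewer degrees of freedom than `free`; not nested")
  }
  fi_f <- free$fit_indices %||% fit_indices(free)
  fi_r <- restricted$fit_indices %||% fit_indices(restricted)
  d_cfi <- fi_r$cfi - fi_f$cfi
  d_rmsea <- fi_r$rmsea - fi_f$rmsea
  if (is.na(d_rmsea)) d_rmsea <- 0 # df = 0 free model: RMSEA undefined
  verdict <- if (-d_cfi > delta_cfi || d_rmsea > delta_rmsea) {
    "depreciated"
  } else {
    "equivalent"
  }
  structure(
    tibble::tibble(
      delta_chi2 = restricted$chi2 - free$chi2,
      delta_df = restricted$df - free$df,
      delta_cfi = d_cfi,
      delta_rmsea = d_rmsea,
      delta_aic = fi_r$aic - fi_f$aic,
      verdict = verdict
    ),
    class = c("comparison_verdict", class(tibble::tibble()))
  )
}
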