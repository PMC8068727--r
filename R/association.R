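#' Regress an outcome on a polygenic score with ancestry-PC covariates
#'
#' Ordinary least squares of the outcome on the predictor plus the ancestry
#' principal components, on complete cases. Reports the unstandardized
#' coefficient with its standard error, the standardized coefficient, the
#' full-model R-squared, the covariates-only R-squared, their difference
#' (incremental R-squared — the standard polygenic-score performance
#' metric), and the adjusted R-squared of the full model.
#'
#' @param data Data frame holding outcome, predictor and PC columns.
#' @param outcome,predictor Column names.
#' @param pcs Character vector of covariate column names (default
#'   `PC1...PC10`).
#' @return An `assoc_result` tibble row.
#' @export
regress_with_pcs <- function(data, outcome, predictor,
                             pcs = paste0("PC", 1:10)) {
  data <- as.data.frame(data)
  need <- c(outcome, predictor, pcs)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(sprintf("data lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  d <- data[complete.cases(data[, need, drop = FALSE]), need, drop = FALSE]
  n <- nrow(d)
  if (n <= length(need) + 2) abort("too few complete cases for regression")
  x_full <- as.matrix(cbind(1, d[, c(predictor, pcs), drop = FALSE]))
  qrx <- qr(x_full)
  if (qrx$rank < ncol(x_full)) {
    bad <- colnames(x_full)[qrx$pivot[(qrx$rank + 1):ncol(x_full)]]
    abort(sprintf("rank-deficient design; offending column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  f_full <- lm(stats::reformulate(c(predictor, pcs), response = outcome),
               data = d)
  f_cov <- lm(stats::reformulate(pcs, response = outcome), data = d)
  sm <- summary(f_full)
  b <- coef(f_full)[[predictor]]
  se <- sm$coefficients[predictor, "Std. Error"]
  r2_full <- sm$r.squared
  r2_cov <- summary(f_cov)$r.squared
  structure(
    tibble::tibble(
      predictor = predictor, outcome = outcome,
      b = b, se = se,
      beta_std = b * sd(d[[predictor]]) / sd(d[[outcome]]),
      p = sm$coefficients[predictor, "Pr(>|t|)"],
      r2_full = r2_full, r2_covariates_only = r2_cov,
      r2_incremental = r2_full - r2_cov,
      adj_r2 = sm$adj.r.squared,
      n = n
    ),
    class = c("assoc_result", class(tibble::tibble()))
  )
}

#' Minimum detectable effect size for a regression predictor
#'
#' Solves for the Cohen's f-squared at which a noncentral-F test of
#' `k_tested` predictors (df1 = k_tested, df2 = n - k_total - 1,
#' noncentrality `f2 * n`) attains the requested power at level `alpha`,
#' converts it to `R2 = f2 / (1 + f2)`, and applies the adjusted-R-squared
#' correction `1 - (1 - R2)(n - 1)/(n - k_total - 1)`. Useful as a
#' power-based interpretability gate for polygenic-score association
#' models; all predictor-count configurations are exposed because the gate
#' depends on them.
#'
#' @param n Sample size.
#' @param alpha Type-I error rate.
#' @param power Target power.
#' @param k_total Total number of predictors in the full model.
#' @param k_tested Number of predictors whose contribution is tested.
#' @param adjusted Apply the adjusted-R-squared correction (default TRUE).
#' @return The detectable threshold (adjusted R-squared scale when
#'   `adjusted`).
#' @export
#' @examples
#' min_detectable_r2(n = 3003, k_total = 11, k_tested = 1)
min_detectable_r2 <- function(n, alpha = 0.05, power = 0.80,
                              k_total = 11L, k_tested = 1L,
                              adjusted = TRUE) {
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must be in (0, 1)")
  if (!(power > 0 && power < 1)) abort("`power` must be in (0, 1)")
  if (!(k_tested <= k_total && k_total < n - 1)) {
    abort("need k_tested <= k_total < n - 1")
  }
  df1 <- k_tested
  df2 <- n - k_total - 1
  crit <- qf(1 - alpha, df1, df2)
  pow_fn <- function(f2) 1 - pf(crit, df1, df2, ncp = f2 * n) - power
  if (pow_fn(1e4) < 0) abort("requested power unreachable for this design")
  f2 <- if (pow_fn(1e-12) >= 0) {
    0 # any non-zero effect already attains the requested power
  } else {
    uniroot(pow_fn, c(1e-12, 1e4), tol = 1e-12)$root
  }
  r2 <- f2 / (1 + f2)
  if (adjusted) 1 - (1 - r2) * (n - 1) / (n - k_total - 1) else r2
}

#' Plot an association report
#'
#' Dot-and-error-bar display of unstandardized effects per
#' predictor-outcome pair.
#'
#' @param object A tibble of stacked `assoc_result` rows.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_associations <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$b, y = .data$predictor)
  ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$b - .data$se, xmax = .data$b + .data$se)
    ) +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::labs(x = "unstandardized effect (b ± SE)", y = NULL) +
    ggplot2::theme_minimal()
}
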