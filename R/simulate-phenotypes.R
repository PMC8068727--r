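#' Specify the generating common-factor model for phenotype panels
#'
#' Defines the measurement model behind [simulate_phenotype_panel()]: factor
#' loadings, group-specific indicator intercepts, residual standard
#' deviations, group-specific factor scale, and an MCAR missingness rate.
#' Group-specific intercepts or factor scales plant known violations of
#' scalar or metric invariance for calibration of the invariance ladder.
#'
#' @param indicators Character vector of indicator names.
#' @param loadings Numeric vector (one factor) or matrix (indicators x
#'   factors) of loadings on the standardized-indicator scale.
#' @param factor_corr Factor correlation matrix (identity by default).
#' @param intercepts_by_group Matrix (groups x indicators) of indicator
#'   intercepts; a single row is recycled to all groups. Default all zero.
#' @param residual_sd Per-indicator residual standard deviation (> 0). The
#'   default completes each indicator to unit total variance.
#' @param factor_sd_by_group Matrix (groups x factors) of factor standard
#'   deviations; default 1.
#' @param missing_rate MCAR missingness fraction in `[0, 1)`.
#' @param group_names Optional group labels (otherwise `g1`, `g2`, ...).
#' @param nuisance_loadings Optional per-indicator loadings on one extra
#'   nuisance dimension that is not part of the target structure.
#'   Population data then depart from both the one- and two-factor models,
#'   emulating the approximation error real questionnaire panels show
#'   (every fitted model has positive population RMSEA).
#'
#' @return An object of class `pheno_truth`.
#' @export
pheno_truth <- function(indicators, loadings, factor_corr = NULL,
                        intercepts_by_group = NULL, residual_sd = NULL,
                        factor_sd_by_group = NULL, missing_rate = 0,
                        group_names = NULL, nuisance_loadings = NULL) {
  p <- length(indicators)
  if (is.vector(loadings)) loadings <- matrix(loadings, ncol = 1L)
  if (nrow(loadings) != p) abort("`loadings` must have one row per indicator.")
  k <- ncol(loadings)
  factor_corr <- factor_corr %||% diag(k)
  if (!is.null(nuisance_loadings) && length(nuisance_loadings) != p) {
    abort("`nuisance_loadings` must have one value per indicator")
  }
  common <- diag(loadings %*% factor_corr %*% t(loadings)) +
    if (is.null(nuisance_loadings)) 0 else nuisance_loadings^2
  if (is.null(residual_sd)) {
    if (any(common > 1)) {
      abort("default unit-variance residuals need communalities <= 1")
    }
    residual_sd <- sqrt(1 - common)
  }
  if (any(residual_sd <= 0)) abort("`residual_sd` must be positive.")
  if (missing_rate < 0 || missing_rate >= 1) abort("`missing_rate` in [0, 1).")
  intercepts_by_group <- intercepts_by_group %||% matrix(0, 1, p)
  if (is.vector(intercepts_by_group)) {
    intercepts_by_group <- matrix(intercepts_by_group, 1, p)
  }
  if (ncol(intercepts_by_group) != p) {
    abort("`intercepts_by_group` must have one column per indicator.")
  }
  n_groups <- nrow(intercepts_by_group)
  factor_sd_by_group <- factor_sd_by_group %||% matrix(1, n_groups, k)
  if (is.vector(factor_sd_by_group)) {
    factor_sd_by_group <- matrix(factor_sd_by_group, ncol = k)
  }
  group_names <- group_names %||% paste0("g", seq_len(n_groups))
  structure(
    list(
      indicators = indicators, loadings = loadings, factor_corr = factor_corr,
      intercepts_by_group = intercepts_by_group,
      residual_sd = residual_sd,
      factor_sd_by_group = factor_sd_by_group,
      missing_rate = missing_rate, group_names = group_names,
      nuisance_loadings = nuisance_loadings
    ),
    class = "pheno_truth"
  )
}

#' Simulate a phenotype panel under a common-factor model
#'
#' Each indicator is `intercept(group) + loading x factor + residual`, with
#' group-specific factor scale and intercepts from the `pheno_truth`;
#' missing entries are inserted completely at random.
#'
#' @param n_individuals Number of rows.
#' @param truth A [pheno_truth()].
#' @param groups Label vector of length `n_individuals`; labels must match
#'   the truth's `group_names` (a single label is recycled).
#' @param seed Integer seed.
#'
#' @return A tibble with `id`, `group` and one column per indicator. The
#'   generating factor scores are attached as attribute `"truth_scores"`.
#' @export
#' @examples
#' tr <- pheno_truth(c("a", "b", "c"), c(0.9, 0.8, 0.7))
#' head(simulate_phenotype_panel(100, tr, "g1", seed = 1))
simulate_phenotype_panel <- function(n_individuals, truth, groups, seed) {
  stop_if_not_count(n_individuals, "n_individuals")
  if (!inherits(truth, "pheno_truth")) abort("`truth` must be a pheno_truth.")
  if (length(groups) == 1L) groups <- rep(groups, n_individuals)
  if (length(groups) != n_individuals) {
    abort("`groups` must have one label per individual.")
  }
  gi <- match(groups, truth$group_names)
  if (anyNA(gi)) {
    abort(sprintf(
      "unknown group label(s): %s",
      paste(unique(groups[is.na(gi)]), collapse = ", ")
    ))
  }
  p <- length(truth$indicators)
  k <- ncol(truth$loadings)
  out <- with_seed(seed, {
    f <- matrix(rnorm(n_individuals * k), n_individuals, k) %*%
      chol(truth$factor_corr)
    f <- f * truth$factor_sd_by_group[gi, , drop = FALSE]
    y <- f %*% t(truth$loadings) +
      matrix(rnorm(n_individuals * p), n_individuals, p) %*%
        diag(truth$residual_sd, p) +
      truth$intercepts_by_group[gi, , drop = FALSE]
    if (!is.null(truth$nuisance_loadings)) {
      y <- y + tcrossprod(rnorm(n_individuals), truth$nuisance_loadings)
    }
    if (truth$missing_rate > 0) {
      y[matrix(runif(n_individuals * p) < truth$missing_rate,
               n_individuals, p)] <- NA_real_
    }
    list(y = y, f = f)
  })
  colnames(out$y) <- truth$indicators
  res <- tibble::tibble(
    id = sprintf("id%06d", seq_len(n_individuals)),
    group = groups
  )
  res <- dplyr::bind_cols(res, tibble::as_tibble(out$y))
  attr(res, "truth_scores") <- out$f
  res
}
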