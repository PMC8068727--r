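#' Age-band grouping
#'
#' Assigns ages to the three bands used for invariance testing in older
#' adults: middle age (51-64), young-old (65-74) and old-old (75-83).
#' Ages outside 51-83 become `NA`.
#'
#' @param age Numeric vector of ages in years.
#' @return A factor with levels `"51-64"`, `"65-74"`, `"75-83"`.
#' @export
#' @examples
#' age_bands(c(55, 70, 80, 90))
age_bands <- function(age) {
  cut(age, breaks = c(51, 65, 75, 84), right = FALSE,
      labels = c("51-64", "65-74", "75-83"))
}

#' Four-level measurement-invariance ladder
#'
#' Fits the nested multi-group sequence — configural (same structure, all
#' parameters free per group), metric (equal loadings), scalar (equal
#' loadings and intercepts), residual (plus equal residual variances) — and
#' compares each level to the previous with [compare_models()]. The ladder's
#' `highest_level_attained` is the last level before any depreciation.
#'
#' @param data Data frame with indicator columns and the grouping variable.
#' @param spec A [factor_model_spec()].
#' @param grouping Name of the grouping column in `data`, or a label vector
#'   of length `nrow(data)`.
#' @param estimator Passed to [fit_cfa()].
#' @param ... Passed to [fit_cfa()] (e.g. `missing`).
#' @return An `invariance_report`: per-level fits and verdicts plus
#'   `highest_level_attained`.
#' @export
invariance_ladder <- function(data, spec, grouping,
                              estimator = c("ml_robust", "ml"), ...) {
  estimator <- match.arg(estimator)
  data <- as.data.frame(data)
  if (length(grouping) == 1L && is.character(grouping) &&
      grouping %in% names(data)) {
    gcol <- grouping
  } else {
    if (length(grouping) != nrow(data)) {
      abort("`grouping` must be a column name or one label per row")
    }
    data$.group <- as.character(grouping)
    gcol <- ".group"
  }
  data <- data[!is.na(data[[gcol]]), , drop = FALSE]
  tab <- table(data[[gcol]])
  if (length(tab) < 2) abort("invariance testing needs at least 2 groups")
  too_small <- names(tab)[tab < length(spec$indicators) + 2]
  if (length(too_small)) {
    abort(sprintf("group(s) too small to fit the configural model: %s",
                  paste(too_small, collapse = ", ")))
  }
  levels_ <- c("configural", "metric", "scalar", "residual")
  fits <- list()
  verdicts <- list()
  for (lv in levels_) {
    fits[[lv]] <- fit_cfa(data, spec, estimator = estimator, group = gcol,
                          level = lv, ...)
  }
  attained <- "configural"
  broken <- FALSE
  for (i in 2:4) {
    v <- compare_models(fits[[levels_[i - 1]]], fits[[levels_[i]]])
    verdicts[[levels_[i]]] <- v
    if (!broken && v$verdict == "equivalent") {
      attained <- levels_[i]
    } else {
      broken <- TRUE
    }
  }
  structure(
    list(fits = fits, verdicts = verdicts,
         highest_level_attained = attained,
         groups = names(tab)),
    class = "invariance_report"
  )
}

#' @export
print.invariance_report <- function(x, ...) {
  cat("<invariance_report> groups:", paste(x$groups, collapse = ", "), "\n")
  for (lv in names(x$verdicts)) {
    v <- x$verdicts[[lv]]
    cat(sprintf("  %-10s dCFI = %+.4f  dRMSEA = %+.4f  -> %s\n",
                lv, v$delta_cfi, v$delta_rmsea, v$verdict))
  }
  cat("  highest level attained:", x$highest_level_attained, "\n")
  invisible(x)
}

#' @rdname tidy_latentpgs
#' @export
tidy.invariance_report <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$verdicts), function(lv) {
    dplyr::mutate(x$verdicts[[lv]], level = lv, .before = 1)
  }))
}

#' Screen indicators with negative loadings
#'
#' Fits the model and flags any indicator whose standardized loading is
#' negative; flagged indicators are dropped and the model refitted without
#' them (mirroring the handling of a reversed indicator such as drinking
#' frequency in a psychopathology panel).
#'
#' @param data Indicator data frame.
#' @param spec A [factor_model_spec()].
#' @param ... Passed to [fit_cfa()].
#' @return A list: `spec` (possibly reduced), `dropped` (character),
#'   `fit` (refit on the reduced spec, or the original fit).
#' @export
screen_negative_loadings <- function(data, spec, ...) {
  fit <- fit_cfa(data, spec, ...)
  std <- standardized_solution(fit)
  neg <- unique(std$indicator[std$mat == "lambda" & std$std_estimate < 0])
  if (length(neg) == 0) {
    return(list(spec = spec, dropped = character(0), fit = fit))
  }
  kept <- setdiff(spec$indicators, neg)
  pattern <- lapply(spec$pattern, function(ind) setdiff(ind, neg))
  pattern <- pattern[vapply(pattern, length, 0L) > 0]
  spec2 <- factor_model_spec(
    indicators = kept, loadings = pattern, factor_cov = spec$factor_cov,
    mean_structure = spec$mean_structure,
    identification = spec$identification
  )
  list(spec = spec2, dropped = neg, fit = fit_cfa(data, spec2, ...))
}
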