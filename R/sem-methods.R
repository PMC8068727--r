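#' Standardized solution of a fitted model
#'
#' Loadings rescaled to the standardized metric (`lambda sd(F) / sd(y)`),
#' factor covariances as correlations, residual variances as fractions of
#' total indicator variance.
#'
#' @param fit A `sem_fit`.
#' @return A tibble: group, mat, indicator/factor names, std_estimate.
#' @export
standardized_solution <- function(fit) {
  out <- list()
  for (gi in seq_along(fit$matrices)) {
    mats <- fit$matrices[[gi]]
    sig <- fit$implied[[gi]]$sigma
    sd_y <- sqrt(pmax(diag(sig), 1e-300))
    k <- ncol(mats$lambda)
    if (k > 0) {
      sd_f <- sqrt(pmax(diag(mats$psi), 1e-300))
      lam_std <- mats$lambda * rep(sd_f, each = nrow(mats$lambda)) / sd_y
      for (ki in seq_len(k)) {
        load_on <- which(mats$lambda[, ki] != 0 | lam_std[, ki] != 0)
        out[[length(out) + 1L]] <- tibble::tibble(
          group = gi, mat = "lambda",
          indicator = rownames(mats$lambda)[load_on],
          factor = colnames(mats$lambda)[ki],
          std_estimate = lam_std[load_on, ki]
        )
      }
      if (k > 1) {
        pc <- stats::cov2cor(mats$psi)
        idx <- which(lower.tri(pc), arr.ind = TRUE)
        out[[length(out) + 1L]] <- tibble::tibble(
          group = gi, mat = "psi",
          indicator = colnames(mats$psi)[idx[, 2]],
          factor = rownames(mats$psi)[idx[, 1]],
          std_estimate = pc[idx]
        )
      }
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      group = gi, mat = "theta",
      indicator = fit$spec$indicators,
      factor = NA_character_,
      std_estimate = mats$theta / diag(sig)
    )
  }
  dplyr::bind_rows(out)
}

#' Tidiers for latentpgs result objects
#'
#' Broom-style [generics::tidy()] methods returning one row per parameter,
#' stage or level.
#'
#' @param x A fitted or report object.
#' @param ... Unused.
#' @name tidy_latentpgs
NULL

#' @rdname tidy_latentpgs
#' @export
tidy.sem_fit <- function(x, ...) {
  pt <- x$ptab
  est <- ifelse(pt$free > 0, x$theta[pt$free], pt$value)
  se <- ifelse(pt$free > 0, x$se[pt$free], NA_real_)
  se_r <- ifelse(pt$free > 0, x$se_robust[pt$free], NA_real_)
  name_of <- function(mat, row, col) {
    ind <- x$spec$indicators
    fac <- x$spec$factors
    switch(mat,
      lambda = sprintf("%s =~ %s", fac[col], ind[row]),
      psi = if (row == col) sprintf("var(%s)", fac[row]) else
        sprintf("cov(%s, %s)", fac[row], fac[col]),
      theta = sprintf("resid(%s)", ind[row]),
      nu = sprintf("intercept(%s)", ind[row]),
      alpha = sprintf("mean(%s)", fac[row])
    )
  }
  tibble::tibble(
    term = mapply(name_of, pt$mat, pt$row, pt$col),
    group = names(x$stats)[pt$group],
    matrix = pt$mat,
    estimate = est,
    std.error = se,
    robust.std.error = se_r,
    free = pt$free > 0
  )
}

#' Model-level summary of a fitted factor model
#'
#' @param x A `sem_fit`.
#' @param ... Unused.
#' @return A one-row tibble: chi-square (raw and scaled), df, fit indices,
#'   AIC, log-likelihood, convergence and Heywood flags.
#' @export
glance.sem_fit <- function(x, ...) {
  fi <- x$fit_indices %||% fit_indices(x)
  tibble::tibble(
    chi2 = x$chi2, chi2_scaled = x$chi2_scaled, df = x$df,
    p.value = if (x$df > 0) pchisq(fi$chi2, x$df, lower.tail = FALSE) else NA,
    cfi = fi$cfi, tli = fi$tli, rmsea = fi$rmsea,
    rmsea_lower = fi$rmsea_lower, rmsea_upper = fi$rmsea_upper,
    srmr = fi$srmr, aic = fi$aic, loglik = x$loglik,
    npar = x$npar, n_obs = x$n_total,
    converged = x$converged, heywood = x$heywood
  )
}

#' @export
print.sem_fit <- function(x, ...) {
  fi <- x$fit_indices
  cat(sprintf("<sem_fit> %s, %d group(s), n = %d, npar = %d\n",
              x$estimator, length(x$stats), x$n_total, x$npar))
  cat(sprintf("  chi2(%d) = %.3f%s\n", x$df, x$chi2,
              if (is.finite(x$chi2_scaled %||% NA_real_) &&
                  !isTRUE(all.equal(x$chi2_scaled, x$chi2))) {
                sprintf(" (scaled %.3f)", x$chi2_scaled)
              } else ""))
  if (!is.null(fi)) {
    cat(sprintf(
      "  CFI = %.3f  TLI = %.3f  RMSEA = %.3f [%.3f, %.3f]  SRMR = %.3f\n",
      fi$cfi, fi$tli, fi$rmsea, fi$rmsea_lower, fi$rmsea_upper, fi$srmr
    ))
  }
  if (!x$converged) cat("  WARNING: not converged (gradient norm ",
                        format(x$gradient_norm), ")\n", sep = "")
  if (x$heywood) {
    cat("  Heywood case:",
        paste(x$heywood_indicators, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot standardized loadings of a fitted factor model
#'
#' @param object A `sem_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sem_fit <- function(object, ...) {
  std <- standardized_solution(object)
  std <- std[std$mat == "lambda", ]
  ggplot2::ggplot(
    std,
    ggplot2::aes(x = .data$std_estimate, y = .data$indicator,
                 fill = .data$factor)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "standardized loading", y = NULL) +
    ggplot2::theme_minimal()
}
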