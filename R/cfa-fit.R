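# ---- data preparation ------------------------------------------------------

# Per-group sufficient statistics. Complete-data path: n, mean, covariance
# (n - 1 divisor, Wishart convention). FIML path: missingness-pattern groups
# with per-pattern n, mean, ML covariance.
prepare_cfa_data <- function(data, spec, group = NULL,
                             missing = c("auto", "fiml", "listwise")) {
  missing <- match.arg(missing)
  data <- as.data.frame(data)
  miss_ind <- setdiff(spec$indicators, names(data))
  if (length(miss_ind)) {
    abort(sprintf("data lacks indicator column(s): %s",
                  paste(miss_ind, collapse = ", ")))
  }
  if (!is.null(group)) {
    if (!group %in% names(data)) abort(sprintf("no grouping column `%s`", group))
    glab <- as.character(data[[group]])
  } else {
    glab <- rep("all", nrow(data))
  }
  y_all <- as.matrix(data[, spec$indicators, drop = FALSE])
  storage.mode(y_all) <- "double"
  has_na <- anyNA(y_all)
  use_fiml <- (missing == "fiml") || (missing == "auto" && has_na)
  labels <- unique(glab)
  stats <- lapply(labels, function(l) {
    y <- y_all[glab == l, , drop = FALSE]
    if (!use_fiml) {
      y <- y[complete.cases(y), , drop = FALSE]
      n <- nrow(y)
      if (n < length(spec$indicators) + 1) {
        abort(sprintf("group `%s` has too few complete rows (%d)", l, n))
      }
      list(n = n, m = colMeans(y), S = cov(y), y = y)
    } else {
      y <- y[rowSums(!is.na(y)) > 0, , drop = FALSE]
      pat_key <- apply(!is.na(y), 1, paste, collapse = "")
      pats <- lapply(split(seq_len(nrow(y)), pat_key), function(idx) {
        obs <- which(!is.na(y[idx[1], ]))
        yo <- y[idx, obs, drop = FALSE]
        n <- length(idx)
        mo <- colMeans(yo)
        so <- crossprod(sweep(yo, 2, mo)) / n # ML divisor
        list(n = n, obs = obs, m = mo, S = so)
      })
      list(n = nrow(y), patterns = pats, y = y)
    }
  })
  names(stats) <- labels
  list(stats = stats, labels = labels, fiml = use_fiml, p = ncol(y_all))
}

# ---- objective and analytic gradient ---------------------------------------

implied_sigma <- function(mats) {
  s <- mats$lambda %*% mats$psi %*% t(mats$lambda)
  diag(s) <- diag(s) + mats$theta
  list(sigma = s, mu = mats$nu + as.vector(mats$lambda %*% mats$alpha))
}

# value + per-group weight matrices for the chain rule:
#   A_g = dF/dSigma_g (symmetric-derivative form), b_g = dF/dmu_g
cfa_value_parts <- function(theta, ptab, spec, prep, mean_structure) {
  p <- prep$p
  total <- 0
  parts <- vector("list", length(prep$labels))
  for (gi in seq_along(prep$labels)) {
    mats <- ptab_matrices(ptab, theta, spec, gi)
    imp <- implied_sigma(mats)
    st <- prep$stats[[gi]]
    if (!prep$fiml) {
      ch <- tryCatch(chol(imp$sigma), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      is_ <- chol2inv(ch)
      ldet <- 2 * sum(log(diag(ch)))
      s_eff <- st$S
      meanterm <- 0
      if (mean_structure) {
        dm <- st$m - imp$mu
        meanterm <- drop(dm %*% is_ %*% dm)
        s_eff <- s_eff + tcrossprod(dm)
      }
      f <- ldet + sum(is_ * st$S) - determinant(st$S)$modulus[1] - p + meanterm
      w <- st$n - 1
      total <- total + w * f
      a <- is_ %*% (imp$sigma - s_eff) %*% is_
      b <- if (mean_structure) -2 * w * drop(is_ %*% (st$m - imp$mu)) else
        rep(0, p)
      parts[[gi]] <- list(A = w * a, b = b, mats = mats, imp = imp)
    } else {
      # -2 x loglik over missingness patterns (constant included)
      a_full <- matrix(0, p, p)
      b_full <- rep(0, p)
      val <- 0
      for (pt in st$patterns) {
        o <- pt$obs
        so_model <- imp$sigma[o, o, drop = FALSE]
        ch <- tryCatch(chol(so_model), error = function(e) NULL)
        if (is.null(ch)) return(NULL)
        is_ <- chol2inv(ch)
        ldet <- 2 * sum(log(diag(ch)))
        dm <- pt$m - imp$mu[o]
        aa <- pt$S + tcrossprod(dm)
        val <- val + pt$n * (length(o) * log(2 * pi) + ldet + sum(is_ * aa))
        a_full[o, o] <- a_full[o, o] + pt$n * (is_ - is_ %*% aa %*% is_)
        b_full[o] <- b_full[o] - 2 * pt$n * drop(is_ %*% dm)
      }
      total <- total + val
      mats2 <- mats
      parts[[gi]] <- list(A = a_full, b = b_full, mats = mats2, imp = imp)
    }
  }
  list(value = total, parts = parts)
}

# chain rule: accumulate dF/dtheta over groups and shared free ids
cfa_gradient_from_parts <- function(parts, ptab, spec, theta) {
  grad <- numeric(length(theta))
  for (gi in seq_along(parts)) {
    pp <- parts[[gi]]
    a <- pp$A
    lam <- pp$mats$lambda
    psi <- pp$mats$psi
    alp <- pp$mats$alpha
    alp_v <- as.vector(alp)
    alp_mat <- a %*% lam %*% psi # used for lambda derivative (cov part)
    lal <- t(lam) %*% a %*% lam # psi derivative
    subg <- ptab_group(ptab, gi)
    fr <- which(subg$free > 0)
    if (length(fr) == 0) next
    for (r in fr) {
      m <- subg$mat[r]
      i <- subg$row[r]
      j <- subg$col[r]
      id <- subg$free[r]
      g_val <- if (m == "lambda") {
        2 * alp_mat[i, j] + pp$b[i] * alp_v[j]
      } else if (m == "psi") {
        if (i == j) lal[i, i] else 2 * lal[i, j]
      } else if (m == "theta") {
        a[i, i]
      } else if (m == "nu") {
        pp$b[i]
      } else { # alpha
        sum(pp$b * lam[, i])
      }
      grad[id] <- grad[id] + g_val
    }
  }
  grad
}

cfa_start_values <- function(ptab, spec, prep, mean_structure) {
  n_free <- attr(ptab, "n_free")
  theta <- numeric(n_free)
  for (gi in seq_along(prep$labels)) {
    st <- prep$stats[[gi]]
    if (!prep$fiml) {
      v <- diag(st$S)
      m <- st$m
    } else {
      v <- apply(st$y, 2, var, na.rm = TRUE)
      m <- colMeans(st$y, na.rm = TRUE)
    }
    v[!is.finite(v) | v <= 0] <- 1
    sub <- ptab[ptab$group == gi & ptab$free > 0, ]
    for (r in seq_len(nrow(sub))) {
      id <- sub$free[r]
      val <- switch(sub$mat[r],
        lambda = 0.7 * sqrt(v[sub$row[r]]),
        psi = if (sub$row[r] == sub$col[r]) 1 else 0.3,
        theta = 0.5 * v[sub$row[r]],
        nu = m[sub$row[r]],
        alpha = 0
      )
      theta[id] <- val # later groups overwrite shared ids harmlessly
    }
  }
  theta
}

# ---- main fit --------------------------------------------------------------

#' Fit a confirmatory factor model by maximum likelihood
#'
#' Minimizes the ML discrepancy between the model-implied and sample
#' covariance matrices (Wishart form, `chi2 = (n - 1) F` per group), or the
#' full-information likelihood over observed entries when data contain
#' missing values. `estimator = "ml_robust"` (default) additionally computes
#' sandwich standard errors and a mean-scaled (Satorra-Bentler-type)
#' chi-square from the empirical fourth-moment matrix; fit indices are then
#' based on the scaled statistic.
#'
#' Residual variances are unconstrained during optimization; a negative
#' estimate (Heywood case) is flagged in the result, never silently fixed.
#'
#' @param data Data frame with the spec's indicator columns (and the
#'   grouping column for multi-group fits).
#' @param spec A [factor_model_spec()].
#' @param estimator `"ml_robust"` or `"ml"`.
#' @param group Optional name of a grouping column; fits a multi-group
#'   model with cross-group constraints per `level`.
#' @param level Invariance level for multi-group fits: `"configural"`,
#'   `"metric"`, `"scalar"` or `"residual"`.
#' @param missing `"auto"` (FIML when missing values are present),
#'   `"fiml"`, or `"listwise"`.
#'
#' @return A `sem_fit` object; see [tidy.sem_fit()], [glance.sem_fit()].
#' @export
fit_cfa <- function(data, spec, estimator = c("ml_robust", "ml"),
                    group = NULL, level = "configural",
                    missing = c("auto", "fiml", "listwise")) {
  estimator <- match.arg(estimator)
  if (!inherits(spec, "factor_model_spec")) {
    abort("`spec` must be a factor_model_spec")
  }
  prep <- prepare_cfa_data(data, spec, group, missing)
  n_groups <- length(prep$labels)
  mean_structure <- spec$mean_structure || n_groups > 1 || prep$fiml
  ptab <- build_ptab(spec, n_groups, level, mean_structure)
  fit <- fit_sem_internal(ptab, spec, prep, mean_structure, estimator)
  fit$group_labels <- prep$labels
  fit$level <- level
  # baseline (independence) model on the same data
  base_spec <- structure(
    list(indicators = spec$indicators, factors = character(0),
         pattern = list(), factor_cov = "fixed_zero",
         mean_structure = mean_structure,
         identification = "unit_variance", fixed_residuals = NULL),
    class = "factor_model_spec"
  )
  base_ptab <- build_ptab(base_spec, n_groups, "configural", mean_structure)
  base <- fit_sem_internal(base_ptab, base_spec, prep, mean_structure,
                           estimator)
  fit$baseline <- list(
    chi2 = base$chi2, df = base$df, chi2_scaled = base$chi2_scaled,
    loglik = base$loglik, npar = base$npar
  )
  fit$fit_indices <- fit_indices(fit)
  fit
}

fit_sem_internal <- function(ptab, spec, prep, mean_structure, estimator) {
  p <- prep$p
  n_groups <- length(prep$labels)
  npar <- attr(ptab, "n_free")
  n_cov_moments <- n_groups * p * (p + 1) / 2
  n_mean_moments <- if (mean_structure) n_groups * p else 0
  df <- n_cov_moments + n_mean_moments - npar
  if (df < 0) abort("model is not identified (negative degrees of freedom)")

  theta0 <- cfa_start_values(ptab, spec, prep, mean_structure)
  fn <- function(th) {
    out <- cfa_value_parts(th, ptab, spec, prep, mean_structure)
    if (is.null(out)) return(1e10 + sum((th - theta0)^2))
    out$value
  }
  gr <- function(th) {
    out <- cfa_value_parts(th, ptab, spec, prep, mean_structure)
    if (is.null(out)) return(2 * (th - theta0))
    cfa_gradient_from_parts(out$parts, ptab, spec, th)
  }
  if (npar > 0) {
    opt <- optim(theta0, fn, gr, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14))
    theta <- newton_polish(opt$par, fn, gr)
  } else {
    theta <- theta0
  }
  out <- cfa_value_parts(theta, ptab, spec, prep, mean_structure)
  if (is.null(out)) abort("optimizer left the positive-definite region")
  grad <- if (npar > 0) {
    cfa_gradient_from_parts(out$parts, ptab, spec, theta)
  } else {
    numeric(0)
  }
  gnorm <- if (npar > 0) max(abs(grad)) else 0
  scale_ref <- max(1, abs(out$value))
  converged <- gnorm < 1e-4 * scale_ref

  mats <- lapply(seq_len(n_groups), function(g) {
    ptab_matrices(ptab, theta, spec, g)
  })
  implied <- lapply(mats, implied_sigma)

  # chi-square and log-likelihood
  n_vec <- vapply(prep$stats, `[[`, 0, "n")
  if (!prep$fiml) {
    chi2 <- out$value
    loglik <- 0
    for (gi in seq_len(n_groups)) {
      st <- prep$stats[[gi]]
      s <- implied[[gi]]$sigma
      is_ <- solve(s)
      mterm <- if (mean_structure) {
        dm <- st$m - implied[[gi]]$mu
        drop(dm %*% is_ %*% dm)
      } else 0
      loglik <- loglik -
        ((st$n - 1) / 2) * (determinant(s)$modulus[1] + sum(is_ * st$S) +
                              mterm + p * log(2 * pi))
    }
  } else {
    sat <- fiml_saturated_loglik(prep)
    loglik <- -out$value / 2
    chi2 <- 2 * (sat - loglik)
  }

  # Heywood check
  th_rows <- ptab[ptab$mat == "theta" & ptab$free > 0, ]
  heywood_ind <- unique(spec$indicators[
    th_rows$row[theta[th_rows$free] < 0]
  ])
  # admissibility of the factor covariance (correlations inside [-1, 1],
  # psi positive semi-definite) in every group
  psi_ok <- all(vapply(mats, function(mm) {
    k <- ncol(mm$psi)
    if (k == 0) return(TRUE)
    if (any(diag(mm$psi) <= 0)) return(FALSE)
    pc <- stats::cov2cor(mm$psi)
    max(abs(pc[lower.tri(pc)]), 0) <= 1 + 1e-8 &&
      min(eigen(pc, symmetric = TRUE, only.values = TRUE)$values) >= -1e-8
  }, TRUE))

  res <- structure(
    list(
      spec = spec, ptab = ptab, theta = theta, npar = npar, df = df,
      chi2 = max(chi2, 0), chi2_scaled = NA_real_, scaling = NA_real_,
      n_obs = n_vec, n_total = sum(n_vec), loglik = loglik,
      matrices = mats, implied = implied,
      stats = prep$stats, fiml = prep$fiml,
      mean_structure = mean_structure,
      converged = converged, gradient_norm = gnorm,
      heywood = length(heywood_ind) > 0, heywood_indicators = heywood_ind,
      admissible = psi_ok && length(heywood_ind) == 0,
      estimator = estimator
    ),
    class = "sem_fit"
  )
  res <- add_standard_errors(res, ptab, spec, prep, mean_structure, fn)
  res
}

# Newton refinement after BFGS. Near the optimum the objective differences
# fall below floating-point noise, so steps are accepted on gradient-norm
# descent (the analytic gradient stays clean to machine precision).
newton_polish <- function(theta, fn, gr, max_iter = 40, tol = 1e-12) {
  g <- gr(theta)
  g0 <- max(abs(g))
  for (it in seq_len(max_iter)) {
    if (g0 < tol) break
    h <- numeric_jacobian(gr, theta)
    h <- (h + t(h)) / 2
    step <- tryCatch(
      solve(h + diag(1e-10 * max(1, max(abs(diag(h)))), length(theta)), g),
      error = function(e) g * 1e-4
    )
    improved <- FALSE
    for (shrink in 0:30) {
      cand <- theta - step
      g1 <- tryCatch(gr(cand), error = function(e) NULL)
      if (!is.null(g1) && all(is.finite(g1)) && max(abs(g1)) < g0) {
        theta <- cand
        g <- g1
        g0 <- max(abs(g1))
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) break
  }
  theta
}

numeric_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  jac <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x
    xm <- x
    xp[j] <- x[j] + h
    xm[j] <- x[j] - h
    jac[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  jac
}

# saturated-model loglik under missing data (EM for mean and covariance)
fiml_saturated_loglik <- function(prep, maxit = 500, tol = 1e-10) {
  total <- 0
  for (st in prep$stats) {
    y <- st$y
    p <- ncol(y)
    mu <- colMeans(y, na.rm = TRUE)
    sig <- cov(y, use = "pairwise.complete.obs")
    sig[!is.finite(sig)] <- 0
    sig <- psd_smooth(sig, 1e-6)$mat
    ll_old <- -Inf
    for (it in seq_len(maxit)) {
      # E-step: expected sufficient statistics per missingness pattern
      sum_y <- rep(0, p)
      sum_yy <- matrix(0, p, p)
      ll <- 0
      for (pt in fiml_patterns(y)) {
        o <- pt$obs
        mis <- setdiff(seq_len(p), o)
        so <- sig[o, o, drop = FALSE]
        iso <- solve(so)
        yo <- pt$y
        n_pt <- nrow(yo)
        dm <- sweep(yo, 2, mu[o])
        ll <- ll - 0.5 * n_pt * (length(o) * log(2 * pi) +
                                   determinant(so)$modulus[1]) -
          0.5 * sum((dm %*% iso) * dm)
        if (length(mis) == 0) {
          sum_y <- sum_y + colSums(yo)
          sum_yy <- sum_yy + crossprod(yo)
        } else {
          b <- sig[mis, o, drop = FALSE] %*% iso
          ym <- sweep(dm %*% t(b), 2, mu[mis], `+`)
          cond_var <- sig[mis, mis, drop = FALSE] -
            b %*% sig[o, mis, drop = FALSE]
          full <- matrix(0, n_pt, p)
          full[, o] <- yo
          full[, mis] <- ym
          sum_y <- sum_y + colSums(full)
          cp <- crossprod(full)
          cp[mis, mis] <- cp[mis, mis] + n_pt * cond_var
          sum_yy <- sum_yy + cp
        }
      }
      n <- nrow(y)
      mu <- sum_y / n
      sig <- sum_yy / n - tcrossprod(mu)
      sig <- (sig + t(sig)) / 2
      if (abs(ll - ll_old) < tol * (abs(ll) + 1)) break
      ll_old <- ll
    }
    total <- total + ll
  }
  total
}

fiml_patterns <- function(y) {
  key <- apply(!is.na(y), 1, paste, collapse = "")
  lapply(split(seq_len(nrow(y)), key), function(idx) {
    obs <- which(!is.na(y[idx[1], ]))
    list(obs = obs, y = y[idx, obs, drop = FALSE])
  })
}
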