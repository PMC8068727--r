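#' Fit a factor model to a genetic covariance matrix by DWLS
#'
#' Minimizes `(s - sigma(theta))' W (s - sigma(theta))` over the
#' half-vectorized genetic covariance, with `W = diag(1/diag(V))`
#' (diagonally weighted least squares). Standard errors are
#' sandwich-corrected with the full jackknife sampling covariance V; the
#' model chi-square is the mean-scaled residual statistic
#' `df * r'Wr / tr(UV)` with `U = W - W D (D'WD)^-1 D'W`, which has
#' expectation df under a correct model. CFI is computed against the
#' independence model on the same (S, V); AIC follows the
#' `chi2 + 2 npar` convention; SRMR is on the correlation metric.
#'
#' When a residual variance estimate is negative (Heywood case), the model
#' is refitted with that residual fixed to zero and the `heywood_fixed`
#' flag records which trait was constrained.
#'
#' @param gc A `genetic_cov` from [build_genetic_cov()].
#' @param spec A [factor_model_spec()] over `gc$trait_names`.
#' @param estimator Only `"dwls"`.
#' @param heywood_refit Automatically refit with the offending residual
#'   fixed to 0 (default TRUE).
#' @return A `gsem_fit` (shares the `sem_fit` interface).
#' @export
fit_gsem <- function(gc, spec, estimator = "dwls", heywood_refit = TRUE) {
  if (!inherits(gc, "genetic_cov")) abort("`gc` must be a genetic_cov")
  if (!inherits(spec, "factor_model_spec")) {
    abort("`spec` must be a factor_model_spec")
  }
  if (!setequal(spec$indicators, gc$trait_names)) {
    abort("spec indicators must match the genetic covariance traits")
  }
  # reorder spec indicators to gc order
  if (!identical(spec$indicators, gc$trait_names)) {
    spec$indicators <- gc$trait_names
  }
  fit <- fit_gsem_once(gc, spec)
  if (fit$heywood && heywood_refit) {
    fixed <- setNames(rep(0, length(fit$heywood_indicators)),
                      fit$heywood_indicators)
    spec2 <- spec
    spec2$fixed_residuals <- c(spec$fixed_residuals, fixed)
    fit <- fit_gsem_once(gc, spec2)
    fit$heywood <- TRUE
    fit$heywood_fixed <- names(fixed)
  }
  fit
}

fit_gsem_once <- function(gc, spec) {
  t_n <- length(gc$trait_names)
  s_vec <- vech(gc$S)
  v_diag <- pmax(diag(gc$V), 1e-12)
  w_vec <- 1 / v_diag
  idx <- vech_index(t_n)
  q <- length(s_vec)
  # symmetric weight lookup for the gradient chain rule
  wmat <- unvech(w_vec, t_n)

  ptab <- build_ptab(spec, 1L, "configural", FALSE)
  npar <- attr(ptab, "n_free")
  df <- q - npar
  if (df < 0) abort("model is not identified on these traits")

  resid_parts <- function(theta) {
    imp <- implied_sigma(ptab_matrices(ptab, theta, spec, 1L))
    r <- gc$S - imp$sigma
    value <- sum(w_vec * vech(r)^2)
    # tr(A dSigma) form: off-diagonals -w_ij r_ij (doubled by symmetry),
    # diagonal -2 w_ii r_ii
    a <- -wmat * r
    diag(a) <- 2 * diag(a)
    list(value = value, parts = list(list(
      A = a, b = rep(0, t_n),
      mats = ptab_matrices(ptab, theta, spec, 1L), imp = imp
    )), imp = imp)
  }
  fn <- function(th) resid_parts(th)$value
  gr <- function(th) {
    rp <- resid_parts(th)
    cfa_gradient_from_parts(rp$parts, ptab, spec, th)
  }
  theta0 <- gsem_start_values(ptab, spec, gc)
  theta <- if (npar > 0) {
    opt <- optim(theta0, fn, gr, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14))
    newton_polish(opt$par, fn, gr)
  } else {
    theta0
  }
  rp <- resid_parts(theta)
  gnorm <- if (npar > 0) max(abs(gr(theta))) else 0
  converged <- gnorm < 1e-6 * max(1, abs(rp$value))

  mats <- ptab_matrices(ptab, theta, spec, 1L)
  imp <- rp$imp
  mom_fn <- function(th) {
    vech(implied_sigma(ptab_matrices(ptab, th, spec, 1L))$sigma)
  }
  delta <- if (npar > 0) numeric_jacobian(mom_fn, theta) else
    matrix(0, q, 0)
  w_m <- diag(w_vec, q)
  a_mat <- t(delta) %*% w_m %*% delta
  a_inv <- tryCatch(solve(a_mat), error = function(e) NULL)
  r_vec <- s_vec - vech(imp$sigma)
  t_raw <- sum(w_vec * r_vec^2)
  if (!is.null(a_inv) && npar > 0) {
    acov <- a_inv %*% t(delta) %*% w_m %*% gc$V %*% w_m %*% delta %*% a_inv
    se <- sqrt(pmax(diag(acov), 0))
    u <- w_m - w_m %*% delta %*% a_inv %*% t(delta) %*% w_m
    truv <- sum(u * t(gc$V))
    chi2 <- if (df > 0) df * t_raw / truv else 0
  } else {
    acov <- matrix(NA_real_, npar, npar)
    se <- rep(NA_real_, npar)
    truv <- sum(diag(w_m %*% gc$V))
    chi2 <- if (df > 0) t_raw * df / truv else 0
  }

  th_rows <- ptab[ptab$mat == "theta" & ptab$free > 0, ]
  heywood_ind <- unique(spec$indicators[th_rows$row[theta[th_rows$free] < 0]])
  psi_ok <- {
    k <- ncol(mats$psi)
    if (k == 0) TRUE else {
      pc <- tryCatch(stats::cov2cor(mats$psi), error = function(e) NULL)
      !is.null(pc) && (k == 1 || max(abs(pc[lower.tri(pc)])) <= 1 + 1e-8)
    }
  }

  # baseline: diagonal model (exact fit on the diagonal)
  base_df <- q - t_n
  r_base <- gc$S
  diag(r_base) <- 0 # the diagonal model reproduces variances exactly
  t_base <- sum(w_vec * vech(r_base)^2)
  # scale baseline the same way: U_base for the diagonal model
  delta_b <- matrix(0, q, t_n)
  diag_pos <- which(idx[, 1] == idx[, 2])
  for (i in seq_len(t_n)) delta_b[diag_pos[i], i] <- 1
  ab_inv <- solve(t(delta_b) %*% w_m %*% delta_b)
  u_b <- w_m - w_m %*% delta_b %*% ab_inv %*% t(delta_b) %*% w_m
  chi2_base <- base_df * t_base / sum(u_b * t(gc$V))

  sd_s <- sqrt(pmax(diag(gc$S), 1e-300))
  srmr <- sqrt(mean(vech((gc$S - imp$sigma) / outer(sd_s, sd_s))^2))

  fi <- fit_index_block(chi2, df, chi2_base, base_df, gc$m_snps)
  fi$srmr <- srmr
  fi$aic <- chi2 + 2 * npar
  fi$chi2 <- chi2
  fi$df <- df
  fi$n_obs <- gc$m_snps

  structure(
    list(
      spec = spec, ptab = ptab, theta = theta, npar = npar, df = df,
      chi2 = chi2, chi2_scaled = chi2, scaling = 1, t_raw = t_raw,
      truv = truv,
      n_obs = gc$m_snps, n_total = gc$m_snps, loglik = NA_real_,
      matrices = list(mats), implied = list(imp),
      stats = list(all = list(S = gc$S, n = gc$m_snps)),
      fiml = FALSE, mean_structure = FALSE,
      converged = converged, gradient_norm = gnorm,
      heywood = length(heywood_ind) > 0, heywood_indicators = heywood_ind,
      heywood_fixed = character(0),
      admissible = psi_ok && length(heywood_ind) == 0,
      estimator = "dwls",
      se = se, se_robust = se, vcov = acov, vcov_robust = acov,
      baseline = list(chi2 = chi2_base, df = base_df,
                      chi2_scaled = chi2_base),
      fit_indices = fi,
      gc = gc
    ),
    class = c("gsem_fit", "sem_fit")
  )
}

gsem_start_values <- function(ptab, spec, gc) {
  npar <- attr(ptab, "n_free")
  theta <- numeric(npar)
  v <- pmax(diag(gc$S), 0.01)
  sub <- ptab[ptab$free > 0, ]
  for (r in seq_len(nrow(sub))) {
    theta[sub$free[r]] <- switch(sub$mat[r],
      lambda = 0.7 * sqrt(v[sub$row[r]]),
      psi = if (sub$row[r] == sub$col[r]) 1 else 0.3,
      theta = 0.5 * v[sub$row[r]],
      0
    )
  }
  theta
}

#' Compare two nested genetic factor models
#'
#' Mean-scaled difference test on the raw DWLS quadratic forms: the
#' per-model mean-scaled chi-squares are not monotone under nesting
#' (their scaling factors differ), so the comparison scales the
#' *difference* of raw statistics by its own null expectation,
#' `delta_chi2 = (T_r - T_f) * delta_df / (tr(U_r V) - tr(U_f V))` — the
#' DWLS analogue of a Satorra-Bentler scaled difference test. Delta CFI
#' and delta AIC (`delta_chi2 - 2 delta_df`) are derived from it.
#'
#' @param free,restricted Nested `gsem_fit` objects on the same
#'   `genetic_cov`.
#' @return A one-row tibble: `delta_chi2`, `delta_df`, `delta_cfi`,
#'   `delta_aic`, `preferred` (`"free"` or `"restricted"` by AIC).
#' @export
compare_gsem <- function(free, restricted) {
  if (!inherits(free, "gsem_fit") || !inherits(restricted, "gsem_fit")) {
    abort("both arguments must be gsem_fit objects")
  }
  if (restricted$df < free$df) {
    abort("`restricted` has fewer degrees of freedom than `free`; not nested")
  }
  d_df <- restricted$df - free$df
  d_raw <- max(restricted$t_raw - free$t_raw, 0)
  d_truv <- restricted$truv - free$truv
  d_chi2 <- if (d_df == 0 || d_truv <= 0) {
    d_raw # degenerate scaling; report the raw difference
  } else {
    d_raw * d_df / d_truv
  }
  d_cfi <- restricted$fit_indices$cfi - free$fit_indices$cfi
  d_aic <- d_chi2 - 2 * d_df
  tibble::tibble(
    delta_chi2 = d_chi2, delta_df = d_df,
    delta_cfi = d_cfi, delta_aic = d_aic,
    p_value = if (d_df > 0) pchisq(d_chi2, d_df, lower.tail = FALSE) else
      NA_real_,
    preferred = if (d_aic > 0) "free" else "restricted"
  )
}

#' Glance method for genetic factor models
#' @param x A `gsem_fit`.
#' @param ... Unused.
#' @return One-row tibble of fit statistics.
#' @export
glance.gsem_fit <- function(x, ...) {
  fi <- x$fit_indices
  tibble::tibble(
    chi2 = x$chi2, df = x$df,
    p.value = if (x$df > 0) pchisq(x$chi2, x$df, lower.tail = FALSE) else NA,
    cfi = fi$cfi, srmr = fi$srmr, aic = fi$aic,
    npar = x$npar, m_snps = x$n_total,
    converged = x$converged, heywood = x$heywood
  )
}

#' Estimate per-SNP effects on the latent genetic factors
#'
#' For each SNP, the vector of standardized per-SNP trait effects
#' (`z / sqrt(N)`) is regressed on the fitted measurement model by
#' diagonally weighted least squares with the measurement parameters held
#' at their no-SNP estimates: the SNP-trait covariance implied by SNP ->
#' factor regressions `b` is `Lambda b`, so `b` solves a small weighted
#' least-squares problem per SNP. Sampling covariance of the per-SNP trait
#' effects uses the cross-trait LDSC intercept matrix, which carries the
#' dependence induced by sample overlap. Weights are emitted per factor on
#' the per-allele scale (dividing by `sqrt(2 p (1-p))` when allele
#' frequencies are available) so latent polygenic scores are computed by
#' [compute_pgs()] exactly like observed-trait scores.
#'
#' @param gc The `genetic_cov` the model was fitted to.
#' @param fitted A converged `gsem_fit`.
#' @param all_ss The named list of sumstats tibbles (same traits).
#' @return A named list (one element per factor) of `latent_weight_set`
#'   tibbles: `id`, `counted_allele`, `other_allele`, `weight_std`, `se`,
#'   `factor`; SNPs absent from any trait are dropped and counted in the
#'   `n_dropped` attribute.
#' @export
latent_snp_weights <- function(gc, fitted, all_ss) {
  if (!inherits(fitted, "gsem_fit")) abort("`fitted` must be a gsem_fit")
  if (!fitted$converged) abort("latent weights need a converged fit")
  traits <- gc$trait_names
  if (!setequal(names(all_ss), traits)) {
    abort("`all_ss` traits must match the genetic covariance traits")
  }
  all_ss <- all_ss[traits]
  universe <- Reduce(intersect, lapply(all_ss, `[[`, "SNP"))
  n_dropped <- length(unique(unlist(lapply(all_ss, `[[`, "SNP")))) -
    length(universe)
  if (length(universe) == 0) abort("no SNPs shared by every trait")
  ref <- all_ss[[1]][match(universe, all_ss[[1]]$SNP), ]
  t_n <- length(traits)
  z_std <- matrix(NA_real_, length(universe), t_n)
  n_med <- numeric(t_n)
  drop_mask <- rep(FALSE, length(universe))
  for (i in seq_len(t_n)) {
    s <- all_ss[[i]][match(universe, all_ss[[i]]$SNP), ]
    same <- s$A1 == ref$A1 & s$A2 == ref$A2
    flip <- s$A1 == ref$A2 & s$A2 == ref$A1
    drop_mask <- drop_mask | !(same | flip)
    z <- (s$BETA / s$SE) * ifelse(flip, -1, 1)
    z_std[, i] <- z / sqrt(s$N)
    n_med[i] <- stats::median(s$N)
  }
  n_dropped <- n_dropped + sum(drop_mask)
  universe <- universe[!drop_mask]
  z_std <- z_std[!drop_mask, , drop = FALSE]
  ref <- ref[!drop_mask, ]

  lam <- fitted$matrices[[1]]$lambda
  k <- ncol(lam)
  # DWLS: per-trait weight = N / intercept (inverse sampling variance of
  # the standardized effect)
  ints <- diag(gc$intercepts)
  ints[!is.finite(ints) | ints <= 0] <- 1
  w <- n_med / ints
  xtwx <- t(lam) %*% (lam * w)
  proj <- solve(xtwx, t(lam * w)) # k x t
  b <- z_std %*% t(proj) # snps x k
  # sandwich SE with the full intercept-implied sampling covariance
  v_y <- gc$intercepts / sqrt(outer(n_med, n_med))
  v_y[!is.finite(v_y)] <- 0
  diag(v_y) <- ints / n_med
  cov_b <- proj %*% v_y %*% t(proj)
  se <- sqrt(pmax(diag(cov_b), 0))

  frq <- if ("FRQ" %in% names(ref)) ref$FRQ else rep(0.5, nrow(ref))
  scale_raw <- sqrt(pmax(2 * frq * (1 - frq), 1e-12))
  out <- lapply(seq_len(k), function(ki) {
    structure(
      tibble::tibble(
        id = universe,
        counted_allele = ref$A1, other_allele = ref$A2,
        weight_std = b[, ki],
        weight = b[, ki] / scale_raw,
        se = se[ki],
        factor = colnames(lam)[ki]
      ),
      n_dropped = n_dropped,
      class = c("latent_weight_set", class(tibble::tibble()))
    )
  })
  names(out) <- colnames(lam)
  out
}

#' Convert latent weights to a scoring weight table
#'
#' Re-orients each SNP so the weight is non-negative (risk-increasing
#' coding), matching the convention of [harmonize_weights()].
#'
#' @param lws A `latent_weight_set`.
#' @return A weight-table tibble usable by [compute_pgs()].
#' @export
as_weight_table <- function(lws) {
  w <- lws$weight
  counted <- lws$counted_allele
  other <- lws$other_allele
  neg <- w < 0
  w[neg] <- -w[neg]
  tmp <- counted[neg]
  counted[neg] <- other[neg]
  other[neg] <- tmp
  tibble::tibble(
    id = lws$id, counted_allele = counted, other_allele = other,
    weight = w, source = paste0("latent_", lws$factor)
  )
}
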