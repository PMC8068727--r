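# duplication matrix: vec(S) = D %*% vech(S) for symmetric S
duplication_matrix <- function(p) {
  idx <- vech_index(p)
  d <- matrix(0, p * p, nrow(idx))
  for (q in seq_len(nrow(idx))) {
    i <- idx[q, 1]
    j <- idx[q, 2]
    d[(j - 1) * p + i, q] <- 1
    d[(i - 1) * p + j, q] <- 1
  }
  d
}

# stacked model moments: per group [vech(Sigma); mu (if mean structure)]
sem_moment_fn <- function(ptab, spec, n_groups, mean_structure) {
  function(theta) {
    unlist(lapply(seq_len(n_groups), function(g) {
      imp <- implied_sigma(ptab_matrices(ptab, theta, spec, g))
      if (mean_structure) c(vech(imp$sigma), imp$mu) else vech(imp$sigma)
    }))
  }
}

# Sandwich standard errors, Satorra-Bentler-type mean-scaled chi-square.
# Complete-data ML only; FIML falls back to observed-information SEs.
add_standard_errors <- function(res, ptab, spec, prep, mean_structure, fn) {
  npar <- res$npar
  if (npar == 0) {
    res$se <- res$se_robust <- numeric(0)
    res$chi2_scaled <- res$chi2
    res$scaling <- 1
    return(res)
  }
  gr_num <- function(th) {
    out <- cfa_value_parts(th, ptab, spec, prep, mean_structure)
    if (is.null(out)) return(rep(NA_real_, npar))
    cfa_gradient_from_parts(out$parts, ptab, spec, th)
  }
  h <- numeric_jacobian(gr_num, res$theta)
  h <- (h + t(h)) / 2
  acov_ml <- tryCatch(2 * solve(h), error = function(e) {
    matrix(NA_real_, npar, npar)
  })
  res$se <- sqrt(pmax(diag(acov_ml), 0))
  res$vcov <- acov_ml

  if (res$estimator == "ml_robust" && !prep$fiml) {
    p <- prep$p
    n_groups <- length(prep$labels)
    n_total <- res$n_total
    mom_fn <- sem_moment_fn(ptab, spec, n_groups, mean_structure)
    delta <- numeric_jacobian(mom_fn, res$theta)
    q_cov <- p * (p + 1) / 2
    q_g <- q_cov + if (mean_structure) p else 0
    dp <- duplication_matrix(p)

    v_blocks <- list()
    g_blocks <- list()
    w_vec <- numeric(n_groups)
    for (gi in seq_len(n_groups)) {
      st <- prep$stats[[gi]]
      w_g <- st$n / n_total
      w_vec[gi] <- w_g
      sig <- res$implied[[gi]]$sigma
      is_ <- solve(sig)
      v_cov <- 0.5 * t(dp) %*% (is_ %x% is_) %*% dp
      v_g <- if (mean_structure) {
        rbind(cbind(v_cov, matrix(0, q_cov, p)),
              cbind(matrix(0, p, q_cov), is_))
      } else {
        v_cov
      }
      # empirical fourth-moment matrix Gamma
      y <- st$y
      yc <- sweep(y, 2, colMeans(y))
      vi <- vech_index(p)
      d_i <- yc[, vi[, 1], drop = FALSE] * yc[, vi[, 2], drop = FALSE]
      d_full <- if (mean_structure) cbind(d_i, y) else d_i
      gam <- crossprod(sweep(d_full, 2, colMeans(d_full))) / st$n
      v_blocks[[gi]] <- w_g * v_g
      g_blocks[[gi]] <- gam / w_g
    }
    v_w <- block_diag(v_blocks)
    gam_w <- block_diag(g_blocks)
    a_mat <- t(delta) %*% v_w %*% delta
    a_inv <- tryCatch(solve(a_mat), error = function(e) NULL)
    if (!is.null(a_inv)) {
      bread <- t(delta) %*% v_w %*% gam_w %*% v_w %*% delta
      acov_r <- a_inv %*% bread %*% a_inv / n_total
      res$se_robust <- sqrt(pmax(diag(acov_r), 0))
      res$vcov_robust <- acov_r
      if (res$df > 0) {
        u <- v_w - v_w %*% delta %*% a_inv %*% t(delta) %*% v_w
        cc <- sum(u * t(gam_w)) / res$df
        res$scaling <- cc
        res$chi2_scaled <- res$chi2 / cc
      } else {
        res$scaling <- 1
        res$chi2_scaled <- res$chi2
      }
    } else {
      res$se_robust <- res$se
      res$scaling <- NA_real_
      res$chi2_scaled <- res$chi2
    }
  } else {
    # FIML or plain ML: observed-information SEs, unscaled chi-square
    res$se_robust <- res$se
    res$scaling <- if (res$estimator == "ml_robust") NA_real_ else 1
    res$chi2_scaled <- res$chi2
  }
  res
}

block_diag <- function(blocks) {
  sizes <- vapply(blocks, nrow, 0L)
  out <- matrix(0, sum(sizes), sum(sizes))
  at <- 0L
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    out[idx, idx] <- b
    at <- at + nrow(b)
  }
  out
}
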