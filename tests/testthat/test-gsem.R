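# a genetic_cov with known S and simple V, for exact-fit checks
toy_gcov <- function(s_mat, v = NULL) {
  t_n <- nrow(s_mat)
  q <- t_n * (t_n + 1) / 2
  structure(
    list(trait_names = rownames(s_mat), S = s_mat, S_raw = s_mat,
         V = v %||% diag(q) * 1e-4,
         intercepts = diag(t_n),
         m_snps = 1000L, n_blocks = 100L,
         smoothing = list(S_perturbation = 0, V_perturbation = 0)),
    class = "genetic_cov"
  )
}

test_that("an exactly factor-structured S is reproduced with chi2 ~ 0", {
  lam <- c(0.5, 0.4, 0.3, 0.35)
  s <- tcrossprod(lam) + diag(c(0.1, 0.12, 0.2, 0.15))
  dimnames(s) <- list(letters[1:4], letters[1:4])
  fit <- fit_gsem(toy_gcov(s), factor_model_spec(letters[1:4]))
  expect_true(fit$converged)
  expect_equal(abs(fit$matrices[[1]]$lambda[, 1]), lam, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_lt(fit$chi2, 1e-8)
  expect_lt(fit$t_raw, 1e-10)
})

test_that("with identity V the DWLS fit matches a brute-force optimizer", {
  s <- matrix(c(0.30, 0.15, 0.12,
                0.15, 0.25, 0.10,
                0.12, 0.10, 0.28), 3, 3)
  dimnames(s) <- list(c("a", "b", "c"), c("a", "b", "c"))
  gc <- toy_gcov(s, v = diag(6))
  fit <- fit_gsem(gc, factor_model_spec(c("a", "b", "c")))
  # brute force: unweighted least squares over (l1, l2, l3, t1, t2, t3)
  obj <- function(p) {
    imp <- tcrossprod(p[1:3]) + diag(p[4:6])
    sum((s[lower.tri(s, diag = TRUE)] -
           imp[lower.tri(imp, diag = TRUE)])^2)
  }
  brute <- optim(c(0.4, 0.4, 0.4, 0.1, 0.1, 0.1), obj,
                 method = "BFGS", control = list(reltol = 1e-15, maxit = 2000))
  expect_lt(abs(fit$t_raw - brute$value), 1e-8)
  expect_equal(sort(abs(fit$theta[1:3])), sort(abs(brute$par[1:3])),
               tolerance = 1e-4)
})

test_that("a planted negative residual takes the Heywood path", {
  # trait a's communality exceeds its variance: residual must go negative
  lam <- c(0.6, 0.4, 0.3, 0.35)
  s <- tcrossprod(lam) + diag(c(-0.05, 0.1, 0.15, 0.12))
  dimnames(s) <- list(letters[1:4], letters[1:4])
  fit <- fit_gsem(toy_gcov(s), factor_model_spec(letters[1:4]))
  expect_true(fit$heywood)
  expect_equal(fit$heywood_fixed, "a")
  expect_true(fit$converged)
  # the refit honours the constraint
  expect_equal(fit$matrices[[1]]$theta[1], 0)
})

test_that("latent SNP weights obey exact symmetric constructions", {
  lam <- c(0.4, 0.4, 0.4)
  s <- tcrossprod(lam) + diag(0.05, 3)
  dimnames(s) <- list(c("a", "b", "c"), c("a", "b", "c"))
  gc <- toy_gcov(s)
  fit <- fit_gsem(gc, factor_model_spec(c("a", "b", "c")))
  mk_ss <- function(z, n = 10000) {
    tibble::tibble(SNP = sprintf("rs%02d", seq_along(z)), A1 = "A", A2 = "G",
                   BETA = z / sqrt(n), SE = 1 / sqrt(n),
                   P = 2 * pnorm(-abs(z)), N = n, FRQ = 0.5)
  }
  # SNP 1: zero effect everywhere -> weight 0; SNP 2: equal effect b in all
  z <- c(0, 3)
  ss <- list(a = mk_ss(z), b = mk_ss(z), c = mk_ss(z))
  lws <- latent_snp_weights(gc, fit, ss)
  expect_equal(lws$F1$weight_std[1], 0, tolerance = 1e-12)
  # equal loadings, equal effects: weight proportional to b, and invariant
  # to trait permutation
  lws_perm <- latent_snp_weights(gc, fit, ss[c(3, 1, 2)])
  expect_equal(lws$F1$weight_std, lws_perm$F1$weight_std, tolerance = 1e-10)
  # dense grid oracle for the 1-SNP DWLS objective: cov(snp, trait_i) =
  # lambda_i * b, weights equal -> b = sum(lam*y)/sum(lam^2)
  lam_hat <- fit$matrices[[1]]$lambda[, 1]
  y <- (z[2] / sqrt(10000)) / 1
  grid <- seq(-0.2, 0.2, length.out = 40001)
  loss <- vapply(grid, function(b) sum((y - lam_hat * b)^2), numeric(1))
  expect_equal(lws$F1$weight_std[2], grid[which.min(loss)],
               tolerance = 1e-4)
})

test_that("trait permutation leaves gsem fit statistics unchanged", {
  lam <- c(0.5, 0.45, 0.4, 0.3)
  s <- tcrossprod(lam) + diag(c(0.1, 0.08, 0.12, 0.2))
  dimnames(s) <- list(letters[1:4], letters[1:4])
  q <- 10
  v <- diag(q) * 1e-4
  f1 <- fit_gsem(toy_gcov(s), factor_model_spec(letters[1:4]))
  perm <- c(3, 1, 4, 2)
  sp <- s[perm, perm]
  f2 <- fit_gsem(toy_gcov(sp), factor_model_spec(letters[perm]))
  expect_equal(f1$t_raw, f2$t_raw, tolerance = 1e-8)
  expect_equal(f1$chi2, f2$chi2, tolerance = 1e-6)
})
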