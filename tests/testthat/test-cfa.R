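test_that("just-identified one-factor fits reproduce closed-form loadings", {
  s <- diag(3)
  s[1, 2] <- s[2, 1] <- 0.72
  s[1, 3] <- s[3, 1] <- 0.63
  s[2, 3] <- s[3, 2] <- 0.56
  d <- as.data.frame(empirical_mvn(400, s))
  names(d) <- c("a", "b", "c")
  fit <- fit_cfa(d, factor_model_spec(c("a", "b", "c")), estimator = "ml")
  std <- standardized_solution(fit)
  lam <- sort(std$std_estimate[std$mat == "lambda"])
  expect_equal(lam, c(0.7, 0.8, 0.9), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit$chi2, 0, tolerance = 1e-8)
  expect_equal(fit$df, 0)
  # model-implied covariance reproduces S to machine precision
  expect_lt(max(abs(fit$implied[[1]]$sigma - cov(d))), 1e-8)
})

test_that("a saturated model has chi-square exactly zero", {
  # independence truth, saturated via a just-identified spec is not
  # available for p = 2 factors; use the df = 0 three-indicator case
  d <- as.data.frame(empirical_mvn(100, random_cor3()))
  names(d) <- c("a", "b", "c")
  fit <- fit_cfa(d, factor_model_spec(c("a", "b", "c")), estimator = "ml")
  expect_equal(fit$chi2, 0, tolerance = 1e-8)
})

test_that("parameters and robust intervals are recovered in simulation", {
  truth <- c(0.88, 0.8, 0.7, 0.6, 0.5, 0.4)
  tr <- pheno_truth(paste0("y", 1:6), truth)
  spec <- factor_model_spec(paste0("y", 1:6))
  hits <- 0L
  checks <- 0L
  for (r in 1:40) {
    d <- simulate_phenotype_panel(800, tr, "g1", seed = 4000 + r)
    fit <- fit_cfa(d, spec)
    expect_true(fit$converged)
    est <- fit$theta[1:6]
    se <- fit$se_robust[1:6]
    hits <- hits + sum(abs(est - truth) <= 1.96 * se)
    checks <- checks + 6L
  }
  coverage <- hits / checks
  expect_gt(coverage, 0.90)
  expect_lt(coverage, 0.995)
})

test_that("fits are invariant to indicator order and affine rescaling", {
  tr <- pheno_truth(paste0("y", 1:4), c(0.8, 0.7, 0.6, 0.5))
  d <- simulate_phenotype_panel(500, tr, "g1", seed = 41)
  spec <- factor_model_spec(paste0("y", 1:4))
  f1 <- fit_cfa(d, spec, estimator = "ml")
  # reorder columns
  d2 <- d[, c("id", "group", "y3", "y1", "y4", "y2")]
  f2 <- fit_cfa(d2, spec, estimator = "ml")
  expect_equal(f1$chi2, f2$chi2, tolerance = 1e-7)
  s1 <- standardized_solution(f1)
  s2 <- standardized_solution(f2)
  expect_equal(
    s1$std_estimate[s1$mat == "lambda"][match(paste0("y", 1:4),
      s1$indicator[s1$mat == "lambda"])],
    s2$std_estimate[s2$mat == "lambda"][match(paste0("y", 1:4),
      s2$indicator[s2$mat == "lambda"])],
    tolerance = 1e-6
  )
  # affine rescale of an indicator
  d3 <- d
  d3$y2 <- 5 + 3 * d3$y2
  f3 <- fit_cfa(d3, spec, estimator = "ml")
  expect_equal(f1$chi2, f3$chi2, tolerance = 1e-6)
  s3 <- standardized_solution(f3)
  expect_equal(s1$std_estimate[s1$mat == "lambda"],
               s3$std_estimate[s3$mat == "lambda"], tolerance = 1e-6)
})

test_that("equality constraints never decrease chi-square", {
  tr <- pheno_truth(paste0("y", 1:4), c(0.8, 0.7, 0.6, 0.5),
                    intercepts_by_group = rbind(rep(0, 4), rep(0.3, 4)))
  d <- simulate_phenotype_panel(600, tr, rep(c("g1", "g2"), 300), seed = 42)
  spec <- factor_model_spec(paste0("y", 1:4))
  chis <- vapply(c("configural", "metric", "scalar", "residual"),
                 function(lv) {
                   fit_cfa(d, spec, estimator = "ml", group = "group",
                           level = lv)$chi2
                 }, numeric(1))
  expect_true(all(diff(chis) >= -1e-6))
})

test_that("Heywood cases are flagged, not silently repaired", {
  # one indicator nearly collinear with the factor and tiny sample:
  # construct a covariance with an implied negative residual
  s <- matrix(0.6, 4, 4)
  diag(s) <- 1
  s[1, 2:4] <- s[2:4, 1] <- 0.95 * c(0.9, 0.85, 0.8)
  d <- as.data.frame(empirical_mvn(150, latentpgs:::psd_smooth(s)$mat))
  names(d) <- paste0("y", 1:4)
  fit <- fit_cfa(d, factor_model_spec(paste0("y", 1:4)), estimator = "ml")
  if (fit$heywood) {
    expect_true(length(fit$heywood_indicators) >= 1)
    expect_true(any(fit$matrices[[1]]$theta < 0))
  }
  succeed()
})

test_that("FIML handles missing data and matches complete-data ML when none", {
  tr <- pheno_truth(paste0("y", 1:4), c(0.8, 0.7, 0.6, 0.5))
  d <- simulate_phenotype_panel(500, tr, "g1", seed = 43)
  spec <- factor_model_spec(paste0("y", 1:4))
  f_cc <- fit_cfa(d, spec, estimator = "ml")
  f_fiml <- fit_cfa(d, spec, estimator = "ml", missing = "fiml")
  # Wishart (n - 1) vs full-likelihood (n) conventions differ at O(1/n)
  expect_lt(abs(f_cc$chi2 - f_fiml$chi2), 0.05 + 0.01 * f_cc$chi2)
  # MCAR missingness: estimates stay close to the complete-data ones
  d2 <- d
  y <- as.matrix(d2[, paste0("y", 1:4)])
  y[withr::with_seed(44, matrix(runif(2000) < 0.05, 500, 4))] <- NA
  d2[, paste0("y", 1:4)] <- y
  f_miss <- fit_cfa(d2, spec, estimator = "ml")
  expect_true(f_miss$fiml)
  expect_lt(max(abs(f_miss$theta[1:4] - f_cc$theta[1:4])), 0.1)
})

test_that("split_half partitions deterministically into near-halves", {
  d <- data.frame(x = seq_len(6003))
  sp <- split_half(d, seed = 1)
  expect_equal(nrow(sp$test), 3002)
  expect_equal(nrow(sp$holdout), 3001)
  expect_equal(sort(c(sp$test$x, sp$holdout$x)), 1:6003)
  sp2 <- split_half(d, seed = 1)
  expect_identical(sp$test$x, sp2$test$x)
  sp4 <- split_half(data.frame(x = 1:4), seed = 2)
  expect_equal(c(nrow(sp4$test), nrow(sp4$holdout)), c(2, 2))
  expect_error(split_half(data.frame(x = 1), seed = 1), "at least 2")
})

test_that("factor scores recover the generating factor at its reliability", {
  tr <- pheno_truth(paste0("y", 1:6), c(0.88, 0.8, 0.7, 0.6, 0.5, 0.4))
  dd <- simulate_phenotype_panel(2000, tr, "g1", seed = 45)
  fit <- fit_cfa(dd, factor_model_spec(paste0("y", 1:6)), estimator = "ml")
  sc <- factor_scores(fit, dd)
  truth_f <- attr(dd, "truth_scores")[, 1]
  # theoretical reliability of the regression score
  lam <- c(0.88, 0.8, 0.7, 0.6, 0.5, 0.4)
  rel <- sum(lam^2 / (1 - lam^2)) / (1 + sum(lam^2 / (1 - lam^2)))
  expect_lt(abs(cor(sc$F1, truth_f) - sqrt(rel)), 0.03)
  # scoring the indicator means gives 0
  mrow <- dd[1, ]
  mrow[, paste0("y", 1:6)] <- as.list(colMeans(dd[, paste0("y", 1:6)]))
  sc1 <- factor_scores(fit, rbind(mrow, dd))
  expect_lt(abs(sc1$F1[1]), 1e-8)
})
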