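fake_pcs <- function(n, seed = 1) {
  pcs <- withr::with_seed(seed, matrix(rnorm(n * 10), n, 10))
  colnames(pcs) <- paste0("PC", 1:10)
  tibble::as_tibble(pcs)
}

test_that("a planted 1% effect yields ~1% incremental R-squared", {
  n <- 3001
  reps <- 30
  inc <- vapply(seq_len(reps), function(r) {
    d <- fake_pcs(n, seed = 100 + r)
    d$pgs <- withr::with_seed(200 + r, rnorm(n))
    d$outcome <- 0.1 * scale(d$pgs)[, 1] +
      withr::with_seed(300 + r, rnorm(n, sd = sqrt(1 - 0.01)))
    regress_with_pcs(d, "outcome", "pgs")$r2_incremental
  }, numeric(1))
  expect_lt(abs(mean(inc) - 0.01), 3 * sd(inc) / sqrt(reps))
})

test_that("an irrelevant predictor has mean incremental R2 near 1/(n-11)", {
  n <- 400
  reps <- 200
  inc <- vapply(seq_len(reps), function(r) {
    d <- fake_pcs(n, seed = 1000 + r)
    d$pgs <- withr::with_seed(2000 + r, rnorm(n))
    d$outcome <- withr::with_seed(3000 + r, rnorm(n))
    regress_with_pcs(d, "outcome", "pgs")$r2_incremental
  }, numeric(1))
  # E[R2 of one added irrelevant regressor] ~ 1/(n - 11)
  expect_lt(abs(mean(inc) - 1 / (n - 11)), 3 * sd(inc) / sqrt(reps))
})

test_that("deterministic and degenerate regressions behave exactly", {
  n <- 200
  d <- fake_pcs(n)
  d$pgs <- withr::with_seed(5, rnorm(n))
  d$outcome <- d$pgs
  res <- suppressWarnings(regress_with_pcs(d, "outcome", "pgs"))
  expect_equal(res$r2_full, 1, tolerance = 1e-12)
  expect_equal(res$b, 1, tolerance = 1e-10)
  # collinear predictor names the offending column
  d$bad <- d$PC1
  expect_error(regress_with_pcs(d, "outcome", "bad"), "bad|PC1")
})

test_that("standardized beta is affine-invariant and matches semi-partials", {
  n <- 500
  d <- fake_pcs(n, seed = 9)
  d$pgs <- withr::with_seed(10, rnorm(n))
  d$outcome <- 0.2 * d$pgs + 0.1 * d$PC1 + withr::with_seed(11, rnorm(n))
  r1 <- regress_with_pcs(d, "outcome", "pgs")
  d2 <- d
  d2$outcome <- 3 + 5 * d$outcome
  d2$pgs <- -2 + 0.5 * d$pgs
  r2 <- regress_with_pcs(d2, "outcome", "pgs")
  expect_equal(r1$beta_std, r2$beta_std, tolerance = 1e-10)
  expect_equal(r1$r2_incremental, r2$r2_incremental, tolerance = 1e-10)
  # incremental R2 = squared semi-partial via residual-on-residual oracle
  res_out <- resid(lm(outcome ~ ., data = d[, c("outcome",
                                                paste0("PC", 1:10))]))
  res_pgs <- resid(lm(pgs ~ ., data = d[, c("pgs", paste0("PC", 1:10))]))
  semi <- cor(res_out, res_pgs)^2 * var(res_out) /
    var(d$outcome - mean(d$outcome))
  expect_equal(r1$r2_incremental, semi, tolerance = 1e-10)
})

test_that("the minimum detectable R2 matches a noncentral-F oracle", {
  # independent high-precision oracle: golden-section-free grid + refine
  oracle_f2 <- function(n, alpha, power, k_total, k_tested) {
    df1 <- k_tested
    df2 <- n - k_total - 1
    crit <- qf(1 - alpha, df1, df2)
    f <- function(f2) 1 - pf(crit, df1, df2, ncp = f2 * n) - power
    lo <- 1e-10
    hi <- 1
    for (i in 1:400) {
      mid <- sqrt(lo * hi)
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    sqrt(lo * hi)
  }
  for (cfg in list(c(3003, 11, 1), c(3003, 11, 11), c(1000, 5, 1))) {
    f2 <- oracle_f2(cfg[1], 0.05, 0.8, cfg[2], cfg[3])
    r2 <- f2 / (1 + f2)
    adj <- 1 - (1 - r2) * (cfg[1] - 1) / (cfg[1] - cfg[2] - 1)
    expect_equal(
      min_detectable_r2(cfg[1], k_total = cfg[2], k_tested = cfg[3]),
      adj, tolerance = 1e-6
    )
  }
  # monotonicity: doubling n strictly decreases the threshold
  expect_lt(min_detectable_r2(6006, k_total = 11, adjusted = FALSE),
            min_detectable_r2(3003, k_total = 11, adjusted = FALSE))
  # power -> 0 limit: threshold -> 0
  expect_lt(min_detectable_r2(3003, power = 1e-4, k_total = 11,
                              adjusted = FALSE), 1e-3)
  expect_error(min_detectable_r2(3003, alpha = 2), "alpha")
})
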