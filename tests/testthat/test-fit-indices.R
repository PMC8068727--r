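test_that("fit-index arithmetic matches the definitional formulas", {
  # chi2(9) = 70.37 with an invented baseline: CFI = 1 - 61.37/2985
  blk <- fit_index_block(70.37, 9, 3000, 15, 3002)
  expect_equal(blk$cfi, 1 - 61.37 / 2985, tolerance = 1e-12)
  expect_equal(blk$rmsea, sqrt(61.37 / (9 * 3001)), tolerance = 1e-12)
  # chi2 <= df: noncentrality floored at zero
  blk0 <- fit_index_block(5, 9, 3000, 15, 3002)
  expect_equal(blk0$rmsea, 0)
  expect_equal(blk0$cfi, 1)
  # independence model as its own baseline: CFI = 0
  blkb <- fit_index_block(3000, 15, 3000, 15, 3002)
  expect_equal(blkb$cfi, 0)
})

test_that("the RMSEA interval matches an independent noncentral root-finder", {
  # independent oracle: bisection on the noncentral chi-square cdf
  bisect_ncp <- function(x, df, target) {
    if (pchisq(x, df, ncp = 0) < target) return(0)
    lo <- 0
    hi <- max(x * 2, 10)
    while (pchisq(x, df, ncp = hi) > target) hi <- hi * 2
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (pchisq(x, df, ncp = mid) >= target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  for (case in list(c(70.37, 9, 3002), c(46.71, 8, 3002),
                    c(61.96, 9, 3001), c(25, 20, 500))) {
    blk <- fit_index_block(case[1], case[2], 1e5, case[2] + 6, case[3])
    lo <- sqrt(bisect_ncp(case[1], case[2], 0.95) / (case[2] * (case[3] - 1)))
    hi <- sqrt(bisect_ncp(case[1], case[2], 0.05) / (case[2] * (case[3] - 1)))
    expect_equal(blk$rmsea_lower, lo, tolerance = 1e-6)
    expect_equal(blk$rmsea_upper, hi, tolerance = 1e-6)
  }
})

test_that("indices recomputed from stored chi2/df/n reproduce stored values", {
  tr <- pheno_truth(paste0("y", 1:5), c(0.8, 0.75, 0.7, 0.6, 0.5))
  d <- simulate_phenotype_panel(400, tr, "g1", seed = 51)
  fit <- fit_cfa(d, factor_model_spec(paste0("y", 1:5)))
  fi <- fit$fit_indices
  again <- fit_index_block(fi$chi2, fi$df, fit$baseline$chi2_scaled,
                           fit$baseline$df, fit$n_total)
  expect_identical(fi$cfi, again$cfi)
  expect_identical(fi$rmsea, again$rmsea)
  expect_identical(fi$tli, again$tli)
})

test_that("df = 0 models report undefined RMSEA/TLI without NaN", {
  d <- as.data.frame(empirical_mvn(100, random_cor3()))
  names(d) <- c("a", "b", "c")
  fit <- fit_cfa(d, factor_model_spec(c("a", "b", "c")), estimator = "ml")
  fi <- fit$fit_indices
  expect_true(is.na(fi$rmsea))
  expect_true(is.na(fi$tli))
  expect_false(any(is.nan(unlist(fi))))
})

test_that("model comparison applies the delta thresholds", {
  fake_fit <- function(cfi, rmsea, chi2, df, aic) {
    structure(
      list(chi2 = chi2, df = df, n_total = 1000, estimator = "ml",
           fit_indices = tibble::tibble(cfi = cfi, tli = cfi,
                                        rmsea = rmsea, rmsea_lower = NA,
                                        rmsea_upper = NA, srmr = 0.03,
                                        aic = aic, chi2 = chi2, df = df,
                                        n_obs = 1000)),
      class = "sem_fit"
    )
  }
  # the reported one- vs two-factor situation: drop 0.008, rise 0.008
  v <- compare_models(fake_fit(0.988, 0.044, 46.71, 8, 100),
                      fake_fit(0.980, 0.052, 70.37, 9, 110))
  expect_equal(v$verdict, "equivalent")
  expect_equal(v$delta_chi2, 70.37 - 46.71, tolerance = 1e-9)
  # identical fits: all deltas zero
  f <- fake_fit(0.95, 0.05, 50, 10, 80)
  v2 <- compare_models(f, f)
  expect_equal(v2$verdict, "equivalent")
  expect_true(all(abs(c(v2$delta_cfi, v2$delta_rmsea, v2$delta_aic)) == 0))
  # CFI drop beyond 0.01 depreciates
  v3 <- compare_models(fake_fit(0.98, 0.05, 40, 8, 70),
                       fake_fit(0.95, 0.05, 80, 9, 105))
  expect_equal(v3$verdict, "depreciated")
  # RMSEA rise beyond 0.015 depreciates even with stable CFI
  v4 <- compare_models(fake_fit(0.98, 0.04, 40, 8, 70),
                       fake_fit(0.975, 0.06, 60, 9, 88))
  expect_equal(v4$verdict, "depreciated")
  # df ordering guards nesting
  expect_error(compare_models(fake_fit(0.98, 0.04, 40, 9, 70),
                              fake_fit(0.99, 0.03, 30, 8, 60)),
               "fewer degrees of freedom")
})
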