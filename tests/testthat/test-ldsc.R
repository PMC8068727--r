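test_that("LD scores reduce to the self term in linkage equilibrium", {
  g <- simulate_genotypes(3000, snp_panel_spec(60, 60, 0,
                                               maf_range = c(0.2, 0.4)),
                          seed = 71)
  ld <- compute_ld_scores(g, window_snps = 30)
  # bias-adjusted r2 with unlinked SNPs has expectation 0; self term is 1
  expect_lt(max(abs(ld$L2 - 1)), 0.15)
  expect_equal(mean(ld$L2), 1, tolerance = 0.02)
})

test_that("duplicating a SNP column raises its LD score by one", {
  g <- simulate_genotypes(800, snp_panel_spec(20, 20, 0), seed = 72)
  d2 <- cbind(g$dosage, g$dosage[, 1])
  g2 <- toy_genotypes(d2)
  ld1 <- compute_ld_scores(g, window_snps = 25)
  ld2 <- compute_ld_scores(g2, window_snps = 25)
  expect_equal(ld2$L2[1], ld1$L2[1] + 1, tolerance = 1e-6)
})

test_that("windowed LD scores match a brute-force all-pairs oracle", {
  panel <- snp_panel_spec(40, 4, 0.6)
  g <- simulate_genotypes(500, panel, seed = 73)
  w <- 15L
  ld <- compute_ld_scores(g, window_snps = w)
  x <- scale(g$dosage)
  n <- nrow(x)
  oracle <- vapply(1:40, function(j) {
    ks <- max(1, j - w):min(40, j + w)
    r2 <- (crossprod(x[, j], x[, ks]) / (n - 1))^2
    sum(r2 - (1 - r2) / (n - 2))
  }, numeric(1))
  expect_equal(ld$L2, oracle, tolerance = 1e-8)
})

test_that("univariate LDSC is calibrated in the null and degenerate cases", {
  panel <- snp_panel_spec(800, 40, 0.6)
  tr0 <- genetic_truth("a", matrix(0, 1, 1), total_h2 = 0,
                       n_per_trait = 6000)
  gw <- simulate_multitrait_gwas(tr0, panel, seed = 74)
  ref <- simulate_genotypes(1200, panel, seed = 75)
  ld <- compute_ld_scores(ref, window_snps = 80)
  u <- ldsc_univariate(gw$sumstats$a, ld, n_blocks = 40)
  expect_lt(abs(u$h2), 3 * u$h2_se + 0.02)
  expect_lt(abs(u$intercept - 1), 3 * u$intercept_se + 0.05)
  # chi2 identically 1: slope exactly 0
  ss_flat <- gw$sumstats$a
  ss_flat$BETA <- ss_flat$SE
  u0 <- ldsc_univariate(ss_flat, ld, n_blocks = 40)
  expect_equal(u0$h2, 0, tolerance = 1e-10)
  expect_error(ldsc_univariate(gw$sumstats$a[1:50, ], ld), "overlap")
})

test_that("bivariate LDSC is symmetric and self-pairing equals univariate", {
  panel <- snp_panel_spec(800, 40, 0.6)
  tr <- genetic_truth("a", matrix(sqrt(0.35), 1, 1), total_h2 = 0.35,
                      n_per_trait = 8000)
  gw <- simulate_multitrait_gwas(tr, panel, seed = 76)
  ref <- simulate_genotypes(1200, panel, seed = 77)
  ld <- compute_ld_scores(ref, window_snps = 80)
  ss <- gw$sumstats$a
  u <- ldsc_univariate(ss, ld, n_blocks = 40)
  b <- ldsc_bivariate(ss, ss, ld, n_blocks = 40)
  expect_equal(b$gcov, u$h2, tolerance = 0.02)
  expect_equal(b$intercept, u$intercept, tolerance = 0.05)
  # exact argument symmetry
  tr2 <- genetic_truth(c("a", "b"), matrix(sqrt(0.3), 2, 1),
                       total_h2 = c(0.3, 0.3), n_per_trait = c(5000, 5000))
  gw2 <- simulate_multitrait_gwas(tr2, panel, seed = 78)
  b12 <- ldsc_bivariate(gw2$sumstats$a, gw2$sumstats$b, ld, n_blocks = 40)
  b21 <- ldsc_bivariate(gw2$sumstats$b, gw2$sumstats$a, ld, n_blocks = 40)
  expect_equal(b12$gcov, b21$gcov, tolerance = 1e-10)
  expect_equal(b12$intercept, b21$intercept, tolerance = 1e-10)
})

test_that("allele-flipped sumstats are reconciled by sign flips", {
  panel <- snp_panel_spec(600, 30, 0.5)
  tr <- genetic_truth(c("a", "b"), matrix(sqrt(0.3), 2, 1),
                      total_h2 = c(0.3, 0.3), n_per_trait = c(5000, 5000))
  gw <- simulate_multitrait_gwas(tr, panel, seed = 79)
  ref <- simulate_genotypes(1000, panel, seed = 80)
  ld <- compute_ld_scores(ref, window_snps = 60)
  ssb <- gw$sumstats$b
  flip <- withr::with_seed(81, sample(c(TRUE, FALSE), nrow(ssb), TRUE))
  tmp <- ssb$A1[flip]
  ssb$A1[flip] <- ssb$A2[flip]
  ssb$A2[flip] <- tmp
  ssb$BETA[flip] <- -ssb$BETA[flip]
  b_ref <- ldsc_bivariate(gw$sumstats$a, gw$sumstats$b, ld, n_blocks = 30)
  b_flip <- ldsc_bivariate(gw$sumstats$a, ssb, ld, n_blocks = 30)
  expect_equal(b_ref$gcov, b_flip$gcov, tolerance = 1e-10)
})

test_that("the genetic covariance bundle is coherent and serializable", {
  panel <- snp_panel_spec(700, 35, 0.5)
  lam <- matrix(c(sqrt(0.3), sqrt(0.3), 0), 3, 1)
  tr <- genetic_truth(c("a", "b", "c"), lam, total_h2 = c(0.3, 0.3, 0.25),
                      n_per_trait = rep(5000, 3))
  gw <- simulate_multitrait_gwas(tr, panel, seed = 82)
  ref <- simulate_genotypes(1000, panel, seed = 83)
  ld <- compute_ld_scores(ref, window_snps = 60)
  gc <- build_genetic_cov(gw$sumstats, ld, n_blocks = 35)
  expect_equal(gc$S, t(gc$S))
  expect_equal(dim(gc$V), c(6, 6))
  ev <- eigen(gc$V, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) >= -1e-8)
  # independent trait c: off-diagonals with c near 0
  expect_lt(abs(gc$S["a", "c"]), 3 * sqrt(gc$V[3, 3]) + 0.02)
  # trait-order invariance
  gc2 <- build_genetic_cov(gw$sumstats[c(2, 1, 3)], ld, n_blocks = 35)
  expect_equal(gc2$S["a", "b"], gc$S["a", "b"], tolerance = 1e-10)
  expect_equal(diag(gc2$S)[c("a", "b", "c")], diag(gc$S)[c("a", "b", "c")],
               tolerance = 1e-10)
  # YAML round trip
  f <- file.path(withr::local_tempdir(), "gcov.yaml")
  write_genetic_cov(gc, f)
  gc3 <- read_genetic_cov(f)
  expect_equal(gc3$S, gc$S, tolerance = 1e-9)
  expect_equal(gc3$V, gc$V, tolerance = 1e-9)
})
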