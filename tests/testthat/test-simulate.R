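test_that("genotype dosages follow Hardy-Weinberg expectations", {
  panel <- snp_panel_spec(50, 5, 0, maf_range = c(0.5, 0.5))
  g <- simulate_genotypes(10000, panel, seed = 1)
  expect_true(all(g$dosage %in% 0:2))
  # mean dosage per SNP within 3 SE of 2 * maf = 1.0
  se <- sqrt(2 * 0.5 * 0.5 / 10000)
  expect_true(all(abs(colMeans(g$dosage) - 1) < 3 * se))

  mono <- simulate_genotypes(200, snp_panel_spec(10, 2, 0,
                                                 maf_range = c(0, 0)),
                             seed = 2)
  expect_true(all(mono$dosage == 0))
})

test_that("block LD structure separates within- from cross-block correlation", {
  panel <- snp_panel_spec(40, 2, 0.8, maf_range = c(0.2, 0.4))
  g <- simulate_genotypes(20000, panel, seed = 3)
  blocks <- latentpgs:::panel_blocks(panel)
  r <- cor(g$dosage)
  within <- r[blocks[row(r)] == blocks[col(r)] & row(r) < col(r)]
  cross <- r[blocks[row(r)] != blocks[col(r)] & row(r) < col(r)]
  expect_gt(mean(within), mean(abs(cross)))
  expect_lt(mean(abs(cross)), 0.05)
})

test_that("genotype simulation is seed-deterministic and validates inputs", {
  panel <- snp_panel_spec(20, 4, 0.5)
  expect_identical(simulate_genotypes(50, panel, seed = 9),
                   simulate_genotypes(50, panel, seed = 9))
  expect_error(snp_panel_spec(10, 2, 1), "within_block_corr")
  expect_error(snp_panel_spec(-5, 2, 0), "n_snps")
  expect_error(simulate_genotypes(1, panel, seed = 1), "at least 2")
})

test_that("null multi-trait GWAS gives mean chi-square near 1", {
  tr <- genetic_truth(c("a", "b"), matrix(0, 2, 1), total_h2 = c(0, 0),
                      n_per_trait = c(4000, 4000))
  panel <- snp_panel_spec(600, 30, 0.5)
  gw <- simulate_multitrait_gwas(tr, panel, seed = 5)
  chi2 <- (gw$sumstats$a$BETA / gw$sumstats$a$SE)^2
  # block-correlated chi2: effective df ~ number of blocks
  expect_lt(abs(mean(chi2) - 1), 3 * sqrt(2 / 30))
  expect_equal(gw$s_true, matrix(0, 2, 2,
                                 dimnames = list(c("a", "b"), c("a", "b"))))
})

test_that("a duplicated trait reproduces itself exactly", {
  lam <- matrix(c(sqrt(0.3), sqrt(0.3)), 2, 1)
  n <- c(3000, 3000)
  tr <- genetic_truth(c("x", "x_copy"), lam, total_h2 = c(0.3, 0.3),
                      n_per_trait = n,
                      pairwise_overlap = matrix(c(3000, 3000, 3000, 3000), 2),
                      env_corr = matrix(1, 2, 2))
  gw <- simulate_multitrait_gwas(tr, snp_panel_spec(500, 25, 0.5), seed = 8)
  # identical up to the jitter used to keep the env covariance factorizable
  expect_equal(gw$sumstats$x$BETA, gw$sumstats$x_copy$BETA, tolerance = 1e-3)
  expect_gt(cor(gw$sumstats$x$BETA, gw$sumstats$x_copy$BETA), 0.999999)
  expect_equal(gw$overlap_realized[1, 2], 3000)
})

test_that("invalid genetic truths are rejected with diagnostics", {
  expect_error(
    genetic_truth(c("a", "b"), matrix(c(1, 1), 2, 1), total_h2 = c(0.5, 0.5),
                  n_per_trait = c(100, 100)),
    "more common genetic variance"
  )
  expect_error(
    genetic_truth(c("a", "b"), matrix(0, 2, 1), total_h2 = c(0.1, 0.1),
                  n_per_trait = c(100, 100),
                  pairwise_overlap = matrix(c(100, 500, 500, 100), 2)),
    "overlap"
  )
})

test_that("phenotype panel matches its generating factor model", {
  # no common factor: correlations near identity
  tr0 <- pheno_truth(paste0("y", 1:4), rep(0, 4))
  d0 <- simulate_phenotype_panel(4000, tr0, "g1", seed = 1)
  r0 <- cor(as.matrix(d0[, paste0("y", 1:4)]))
  expect_lt(max(abs(r0[upper.tri(r0)])), 3 / sqrt(4000))

  # product-of-loadings identity: pop corr(y1, y2) = 0.9 * 0.8 = 0.72
  tr <- pheno_truth(c("a", "b", "c"), c(0.9, 0.8, 0.7))
  d <- simulate_phenotype_panel(5000, tr, "g1", seed = 2)
  se <- (1 - 0.72^2) / sqrt(5000)
  expect_lt(abs(cor(d$a, d$b) - 0.72), 3 * se)

  # covariance converges to Lambda Lambda' + diag(residual variances)
  implied <- tcrossprod(c(0.9, 0.8, 0.7)) +
    diag(1 - c(0.9, 0.8, 0.7)^2)
  expect_lt(max(abs(cov(as.matrix(d[, c("a", "b", "c")])) - implied)), 0.06)

  expect_identical(simulate_phenotype_panel(50, tr, "g1", seed = 7),
                   simulate_phenotype_panel(50, tr, "g1", seed = 7))
  expect_error(simulate_phenotype_panel(10, tr, rep("g1", 5), seed = 1),
               "one label per individual")
})

test_that("group-specific intercepts and missingness are honoured", {
  tr <- pheno_truth(paste0("y", 1:3), c(0.8, 0.7, 0.6),
                    intercepts_by_group = rbind(rep(0, 3), rep(1, 3)),
                    missing_rate = 0.1)
  d <- simulate_phenotype_panel(4000, tr, rep(c("g1", "g2"), 2000), seed = 4)
  y <- as.matrix(d[, paste0("y", 1:3)])
  expect_lt(abs(mean(is.na(y)) - 0.1), 0.02)
  m1 <- colMeans(y[d$group == "g1", ], na.rm = TRUE)
  m2 <- colMeans(y[d$group == "g2", ], na.rm = TRUE)
  expect_true(all(m2 - m1 > 0.8))
})
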