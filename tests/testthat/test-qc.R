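test_that("exact HWE test matches enumeration-based expectations", {
  # (AA=50, Aa=0, aa=50): most extreme heterozygote deficit, p << 1e-4
  expect_lt(hwe_exact_test(50, 0, 50), 1e-10)
  # perfect HWE counts are not rejected
  expect_gt(hwe_exact_test(25, 50, 25), 0.5)
  # independent oracle: full enumeration of the conditional distribution
  oracle <- function(n_aa, n_ab, n_bb) {
    n <- n_aa + n_ab + n_bb
    na <- 2 * n_aa + n_ab
    hets <- seq.int(na %% 2, min(na, 2 * n - na), by = 2)
    pr <- vapply(hets, function(h) {
      ha <- (na - h) / 2
      exp(lchoose(n, ha) + lchoose(n - ha, h) + h * log(2) -
            lchoose(2 * n, na))
    }, numeric(1))
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[match(n_ab, hets)] + 1e-12])
  }
  for (cnt in list(c(10, 5, 3), c(3, 14, 6), c(40, 20, 40), c(1, 1, 30))) {
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-10)
  }
})

test_that("QC removes individuals, low-call-rate SNPs and HWE failures in order", {
  d <- rbind(matrix(2L, 25, 100), matrix(1L, 50, 100), matrix(0L, 25, 100))
  d[, 1:50] <- rbind(matrix(2L, 50, 50), matrix(0L, 50, 50)) # HWE failures
  g <- toy_genotypes(d)
  # individual 1 missing 3 of 100 SNPs (3% > 2%): removed first
  g$dosage[1, 60:62] <- NA
  res <- qc_filter(g)
  expect_equal(res$report$n_individuals_removed, 1)
  expect_equal(res$report$n_snps_removed_callrate, 0)
  expect_equal(res$report$n_snps_removed_hwe, 50)
  expect_false("i001" %in% res$genotypes$sample_meta$id)

  # HWE-consistent complete data: nothing removed
  g2 <- toy_genotypes(rbind(matrix(2L, 25, 4), matrix(1L, 50, 4),
                            matrix(0L, 25, 4)))
  res2 <- qc_filter(g2)
  expect_equal(res2$report$n_individuals_removed +
                 res2$report$n_snps_removed_callrate +
                 res2$report$n_snps_removed_hwe, 0)
})

test_that("individuals are removed before SNP call rates are computed", {
  # SNP 1 is missing only in the bad individual; once that individual is
  # gone its call rate is 1 and it survives
  d <- rbind(matrix(2L, 8, 40), matrix(1L, 15, 40), matrix(0L, 7, 40))
  g <- toy_genotypes(d)
  g$dosage[1, 1:2] <- NA    # 2/40 = 5% > 2% -> individual removed
  res <- qc_filter(g, snp_callrate_min = 0.999)
  expect_equal(res$report$n_individuals_removed, 1)
  expect_equal(res$report$n_snps_removed_callrate, 0)
})

test_that("qc_filter is idempotent", {
  g <- simulate_genotypes(200, snp_panel_spec(60, 6, 0.3,
                                              missing_rate = 0.005), seed = 3)
  once <- qc_filter(g)
  twice <- qc_filter(once$genotypes)
  expect_identical(once$genotypes$dosage, twice$genotypes$dosage)
  expect_equal(twice$report$n_individuals_removed, 0)
  expect_equal(twice$report$n_snps_removed_callrate +
                 twice$report$n_snps_removed_hwe, 0)
})

test_that("QC errors name the stage that removed everything", {
  g <- toy_genotypes(matrix(NA_integer_, 5, 5))
  expect_error(qc_filter(g), "individual-missingness")
  g2 <- toy_genotypes(rbind(matrix(2L, 5, 3), matrix(0L, 5, 3)))
  expect_error(qc_filter(g2, hwe_alpha = 1), "HWE")
})
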