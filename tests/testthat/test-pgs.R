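make_ss <- function(g, beta, a1 = NULL, a2 = NULL) {
  tibble::tibble(
    SNP = g$snp_meta$id,
    A1 = a1 %||% g$snp_meta$a1, A2 = a2 %||% g$snp_meta$a2,
    BETA = beta, SE = 0.1, P = 0.5, N = 1000
  )
}

test_that("harmonization aligns effects to counted alleles and risk-orients", {
  g <- toy_genotypes(matrix(c(0L, 1L, 2L), 3, 1), a1 = "A", a2 = "G")
  # effect allele A with beta -0.3: output counts G with weight +0.3
  ss <- make_ss(g, -0.3)
  w <- harmonize_weights(ss, g)
  expect_equal(w$counted_allele, "G")
  expect_equal(w$weight, 0.3)
  # irreconcilable allele pair dropped and tallied
  g2 <- toy_genotypes(matrix(0L, 3, 2), a1 = c("A", "C"), a2 = c("G", "T"))
  ss2 <- tibble::tibble(SNP = g2$snp_meta$id, A1 = c("A", "A"),
                        A2 = c("G", "G"), BETA = 1, SE = 0.1, P = 0.5,
                        N = 10)
  w2 <- harmonize_weights(ss2, g2)
  expect_equal(nrow(w2), 1)
  expect_equal(attr(w2, "n_mismatched"), 1)
  expect_error(harmonize_weights(ss2[0, ], g2), "empty")
})

test_that("compute_pgs equals the direct weighted allele sum", {
  g <- toy_genotypes(matrix(c(0L, 1L, 2L), 3, 1))
  w <- tibble::tibble(id = "rs001", counted_allele = "A",
                      other_allele = "G", weight = 0.5, source = "t")
  p <- compute_pgs(g, w)
  expect_equal(p$raw_score, c(0, 0.5, 1.0))
  expect_equal(p$n_snps_used, rep(1L, 3))
})

test_that("compute_pgs matches a brute-force double loop exactly", {
  g <- simulate_genotypes(100, snp_panel_spec(50, 10, 0.4), seed = 31)
  # dyadic weights: partial sums exact in binary, so accumulation order
  # cannot matter and equality is exact
  beta <- withr::with_seed(32, round(runif(50, -1, 1) * 1024) / 1024)
  w <- harmonize_weights(make_ss(g, beta), g)
  p <- compute_pgs(g, w)
  brute <- vapply(seq_len(100), function(i) {
    s <- 0
    for (j in seq_len(nrow(w))) {
      jj <- match(w$id[j], g$snp_meta$id)
      dos <- g$dosage[i, jj]
      if (w$counted_allele[j] == g$snp_meta$a2[jj]) dos <- 2L - dos
      s <- s + w$weight[j] * dos
    }
    s
  }, numeric(1))
  expect_identical(p$raw_score, brute)
})

test_that("z-scores are invariant to allele orientation flips", {
  g <- simulate_genotypes(80, snp_panel_spec(40, 8, 0.3), seed = 33)
  beta <- withr::with_seed(34, rnorm(40))
  ss <- make_ss(g, beta)
  flip <- withr::with_seed(35, sample(c(TRUE, FALSE), 40, replace = TRUE))
  ss2 <- ss
  ss2$A1[flip] <- ss$A2[flip]
  ss2$A2[flip] <- ss$A1[flip]
  ss2$BETA[flip] <- -ss$BETA[flip]
  p1 <- compute_pgs(g, harmonize_weights(ss, g))
  p2 <- compute_pgs(g, harmonize_weights(ss2, g))
  expect_equal(p1$z_score, p2$z_score, tolerance = 1e-12)
})

test_that("scores are linear in weights and invariant to SNP order", {
  g <- simulate_genotypes(60, snp_panel_spec(30, 6, 0.3), seed = 36)
  b1 <- withr::with_seed(37, abs(rnorm(30)))
  b2 <- withr::with_seed(38, abs(rnorm(30)))
  w1 <- harmonize_weights(make_ss(g, b1), g)
  w2 <- harmonize_weights(make_ss(g, b2), g)
  wsum <- w1
  wsum$weight <- w1$weight + w2$weight
  expect_equal(compute_pgs(g, wsum)$raw_score,
               compute_pgs(g, w1)$raw_score + compute_pgs(g, w2)$raw_score,
               tolerance = 1e-12)
  perm <- withr::with_seed(39, sample(nrow(w1)))
  expect_equal(compute_pgs(g, w1[perm, ])$raw_score,
               compute_pgs(g, w1)$raw_score, tolerance = 1e-12)
})

test_that("missing-dosage policies behave as documented", {
  d <- matrix(c(0L, 1L, 2L, 2L, NA, 0L), 3, 2)
  g <- toy_genotypes(d)
  w <- tibble::tibble(id = g$snp_meta$id, counted_allele = "A",
                      other_allele = "G", weight = c(1, 0.5), source = "t")
  mi <- compute_pgs(g, w, missing_policy = "mean_impute")
  # SNP2 af among observed = (2 + 0)/4 = 0.5 -> impute dosage 1
  expect_equal(mi$raw_score[2], 1 + 0.5)
  om <- compute_pgs(g, w, missing_policy = "omit")
  expect_equal(om$n_snps_used, c(2L, 1L, 2L))
  # complete data: both policies agree
  g2 <- toy_genotypes(matrix(c(0L, 1L, 2L, 2L, 1L, 0L), 3, 2))
  expect_equal(compute_pgs(g2, w)$raw_score,
               compute_pgs(g2, w, missing_policy = "omit")$raw_score)
})

test_that("normalization is exact, affine-invariant, and errors cleanly", {
  expect_equal(normalize_pgs(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(20)
  expect_equal(normalize_pgs(3 + 2 * x), normalize_pgs(x), tolerance = 1e-12)
  expect_error(normalize_pgs(rep(1, 5)), "zero variance")
  expect_error(normalize_pgs(1), "at least 2")
  # all-zero weights: raw scores 0, z-scoring errors on zero variance
  g <- toy_genotypes(matrix(c(0L, 1L, 2L), 3, 1))
  w <- tibble::tibble(id = "rs001", counted_allele = "A",
                      other_allele = "G", weight = 0, source = "t")
  expect_error(compute_pgs(g, w), "zero variance")
})

test_that("sumstats reader applies column maps and OR transform", {
  f <- file.path(withr::local_tempdir(), "ss.tsv")
  writeLines(c("SNP\tA1\tA2\tOR\tSE\tP\tN",
               "rs1\tA\tG\t1.5\t0.1\t0.01\t500"), f)
  ss <- read_sumstats(f)
  expect_equal(ss$BETA, log(1.5))
  f2 <- file.path(withr::local_tempdir(), "ss2.tsv")
  writeLines(c("rsid\tEA\tOA\tB\tse\tpval\tn",
               "rs1\tA\tG\t0.2\t0.1\t0.01\t500"), f2)
  ss2 <- read_sumstats(f2, col_map = c(SNP = "rsid", A1 = "EA", A2 = "OA",
                                       BETA = "B", SE = "se", P = "pval",
                                       N = "n"))
  expect_equal(ss2$BETA, 0.2)
  expect_warning(latentpgs:::validate_sumstats(dplyr::bind_rows(ss2, ss2)),
                 "duplicate")
})
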