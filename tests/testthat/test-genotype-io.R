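test_that("a hand-written PLINK triplet decodes to the expected dosages", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "toy")
  # 3 samples x 2 SNPs, SNP-major, 2 bits per genotype, low bits first.
  # SNP1: s1 = A1/A1 (00 -> 2), s2 = het (10 -> 1), s3 = A2/A2 (11 -> 0)
  #   byte: 11 10 00 (pad 00) -> 00111000 = 0x38
  # SNP2: s1 missing (01), s2 = A1/A1 (00), s3 = het (10)
  #   byte: 10 00 01 (pad 00) -> 00100001 = 0x21
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x38, 0x21)),
           paste0(prefix, ".bed"))
  writeLines(c("1\trs1\t0\t100\tA\tG", "1\trs2\t0\t200\tC\tT"),
             paste0(prefix, ".bim"))
  writeLines(c("f1\ts1\t0\t0\t0\t-9", "f1\ts2\t0\t0\t0\t-9",
               "f1\ts3\t0\t0\t0\t-9"),
             paste0(prefix, ".fam"))
  g <- read_genotypes(prefix, "plink")
  expect_equal(unname(g$dosage),
               matrix(c(2L, 1L, 0L, NA, 2L, 1L), 3, 2))
  expect_equal(g$snp_meta$a1, c("A", "C"))
})

test_that("PLINK write -> read round-trips dosages and metadata", {
  g <- simulate_genotypes(37, snp_panel_spec(23, 4, 0.4,
                                             missing_rate = 0.05), seed = 6)
  prefix <- file.path(withr::local_tempdir(), "rt")
  write_plink(g, prefix)
  g2 <- read_genotypes(prefix, "plink")
  expect_identical(unname(g$dosage), unname(g2$dosage))
  expect_equal(g2$snp_meta$id, g$snp_meta$id)
  expect_equal(g2$snp_meta$a1, g$snp_meta$a1)
  expect_equal(g2$sample_meta$id, g$sample_meta$id)
})

test_that("degenerate PLINK inputs raise errors, not empty objects", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "bad")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), paste0(prefix, ".bed"))
  writeLines(character(0), paste0(prefix, ".bim"))
  writeLines("f1\ts1\t0\t0\t0\t-9", paste0(prefix, ".fam"))
  expect_error(read_genotypes(prefix, "plink"))
  expect_error(read_genotypes(file.path(dir, "nothere"), "plink"),
               "missing PLINK file")
})

test_that("VCF genotypes are read with ALT as the counted allele", {
  vcf <- file.path(withr::local_tempdir(), "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\trs1\tG\tA\t.\tPASS\t.\tGT\t0/1\t1/1",
    "1\t200\trs2\tT\tC\t.\tPASS\t.\tGT\t0/0\t./."
  ), vcf)
  g <- read_genotypes(vcf, "vcf")
  expect_equal(unname(g$dosage), matrix(c(1L, 2L, 0L, NA), 2, 2))
  expect_equal(g$snp_meta$a1, c("A", "C")) # ALT counted
  expect_equal(g$snp_meta$a2, c("G", "T"))
})
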