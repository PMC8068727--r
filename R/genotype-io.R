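#' Read genotypes from PLINK or VCF files
#'
#' Reads hard-called genotypes into a `genotype_data` object. PLINK input is
#' the binary v1.00 triplet (`.bed` SNP-major with magic bytes
#' `0x6c 0x1b 0x01`, `.bim`, `.fam`); dosages count the `.bim` A1 allele.
#' VCF input (v4.x with a GT field, read via \pkg{vcfR}) counts the ALT
#' allele; records without a hard GT call become missing.
#'
#' @param path For PLINK, the file prefix (without extension); for VCF, the
#'   file path.
#' @param format `"plink"` or `"vcf"`.
#'
#' @return A `genotype_data` object.
#' @export
read_genotypes <- function(path, format = c("plink", "vcf")) {
  format <- match.arg(format)
  if (format == "plink") read_plink(path) else read_vcf_genotypes(path)
}

read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) abort(sprintf("missing PLINK file: %s", f))
  }
  bim_df <- read.table(bim, col.names = c("chr", "id", "cm", "pos", "a1", "a2"),
                       colClasses = c("character", "character", "numeric",
                                      "integer", "character", "character"))
  fam_df <- read.table(fam, col.names = c("fid", "iid", "pat", "mat",
                                          "sex", "pheno"),
                       colClasses = "character")
  m <- nrow(bim_df)
  n <- nrow(fam_df)
  if (m == 0L) abort("empty variant set in .bim")
  if (n == 0L) abort("empty sample set in .fam")
  if (anyDuplicated(bim_df$id)) abort("duplicate SNP ids in .bim")
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    abort("not a PLINK .bed file (bad magic bytes)")
  }
  if (raw[3] != as.raw(0x01)) abort("only SNP-major .bed (v1.00) is supported")
  bpi <- ceiling(n / 4) # bytes per SNP
  body <- raw[-(1:3)]
  if (length(body) != bpi * m) {
    abort(".bed size inconsistent with .bim/.fam dimensions")
  }
  # unpack 2-bit codes: 00 = A1/A1 (dosage 2), 01 = missing, 10 = het, 11 = A2/A2
  ints <- as.integer(body)
  codes <- matrix(0L, 4L * bpi, m)
  shift <- c(0L, 2L, 4L, 6L)
  for (s in 1:4) {
    codes[seq(s, by = 4L, length.out = bpi), ] <-
      matrix(bitwAnd(bitwShiftR(ints, shift[s]), 3L), bpi, m)
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  lut <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  dosage <- matrix(lut[codes + 1L], n, m)
  dimnames(dosage) <- list(fam_df$iid, bim_df$id)
  new_genotype_data(
    dosage,
    tibble::tibble(
      id = bim_df$id, chr = bim_df$chr, pos = bim_df$pos,
      a1 = bim_df$a1, a2 = bim_df$a2
    ),
    tibble::tibble(id = fam_df$iid, group = fam_df$fid)
  )
}

read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) abort(sprintf("missing VCF file: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@gt) == 0L) abort("empty variant set in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(
    fix[is.na(ids) | ids == ".", "CHROM"], ":",
    fix[is.na(ids) | ids == ".", "POS"]
  )
  if (anyDuplicated(ids)) abort("duplicate SNP ids in VCF")
  count_allele <- function(x) {
    a <- strsplit(x, "[/|]")
    vapply(a, function(g) {
      if (length(g) != 2L || any(g == ".") || any(!g %in% c("0", "1"))) {
        return(NA_integer_)
      }
      sum(g == "1")
    }, integer(1))
  }
  dosage <- t(apply(gt, 1, count_allele))
  dimnames(dosage) <- list(ids, colnames(gt))
  dosage <- t(dosage)
  new_genotype_data(
    dosage,
    tibble::tibble(
      id = ids, chr = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
      a1 = fix[, "ALT"], a2 = fix[, "REF"] # counted allele = ALT
    ),
    tibble::tibble(id = colnames(gt), group = NA_character_)
  )
}

#' Write genotypes as a PLINK binary triplet
#'
#' Writes `.bed` (v1.00, SNP-major), `.bim` and `.fam` files; the `.bim` A1
#' column is the counted allele of the `genotype_data`.
#'
#' @param g A `genotype_data` object.
#' @param prefix Output file prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  n <- nrow(g$dosage)
  m <- ncol(g$dosage)
  code <- matrix(1L, n, m) # 01 = missing
  code[which(g$dosage == 2L)] <- 0L
  code[which(g$dosage == 1L)] <- 2L
  code[which(g$dosage == 0L)] <- 3L
  bpi <- ceiling(n / 4)
  padded <- matrix(0L, 4L * bpi, m)
  padded[seq_len(n), ] <- code
  bytes <- padded[seq(1, 4 * bpi, 4), , drop = FALSE] +
    bitwShiftL(padded[seq(2, 4 * bpi, 4), , drop = FALSE], 2L) +
    bitwShiftL(padded[seq(3, 4 * bpi, 4), , drop = FALSE], 4L) +
    bitwShiftL(padded[seq(4, 4 * bpi, 4), , drop = FALSE], 6L)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  sm <- g$snp_meta
  write.table(
    data.frame(sm$chr, sm$id, 0, sm$pos, sm$a1, sm$a2),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  grp <- g$sample_meta$group
  grp[is.na(grp)] <- "0"
  write.table(
    data.frame(grp, g$sample_meta$id, 0, 0, 0, -9),
    paste0(prefix, ".fam"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(prefix)
}
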