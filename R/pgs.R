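#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated file with a header row into the standard sumstats
#' tibble (SNP, A1, A2, BETA, SE, P, N, plus FRQ when present). Column names
#' can be remapped with `col_map`; an odds-ratio column (`OR`) is
#' log-transformed on read.
#'
#' @param path File path.
#' @param col_map Named character vector mapping standard names to the
#'   file's column names, e.g. `c(SNP = "rsid", BETA = "OR")`.
#' @return A sumstats tibble.
#' @export
read_sumstats <- function(path, col_map = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  std <- c(SNP = "SNP", A1 = "A1", A2 = "A2", BETA = "BETA", SE = "SE",
           P = "P", N = "N", FRQ = "FRQ")
  if (!is.null(col_map)) std[names(col_map)] <- col_map
  if (!"BETA" %in% names(col_map %||% character()) && !"BETA" %in% names(df) &&
      "OR" %in% names(df)) {
    std["BETA"] <- "OR"
  }
  need <- c("SNP", "A1", "A2", "BETA", "SE", "P", "N")
  missing_cols <- setdiff(std[need], names(df))
  if (length(missing_cols)) {
    abort(sprintf("sumstats file lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::tibble(
    SNP = as.character(df[[std["SNP"]]]),
    A1 = toupper(df[[std["A1"]]]), A2 = toupper(df[[std["A2"]]]),
    BETA = as.numeric(df[[std["BETA"]]]),
    SE = as.numeric(df[[std["SE"]]]),
    P = as.numeric(df[[std["P"]]]),
    N = as.numeric(df[[std["N"]]])
  )
  if (identical(unname(std["BETA"]), "OR")) out$BETA <- log(out$BETA)
  if (std["FRQ"] %in% names(df)) out$FRQ <- as.numeric(df[[std["FRQ"]]])
  validate_sumstats(out)
}

validate_sumstats <- function(ss) {
  if (any(!ss$A1 %in% c("A", "C", "G", "T")) ||
      any(!ss$A2 %in% c("A", "C", "G", "T"))) {
    abort("sumstats alleles must be A/C/G/T")
  }
  if (any(ss$A1 == ss$A2)) abort("effect and other allele must differ")
  if (any(ss$SE <= 0)) abort("sumstats SE must be > 0")
  if (any(ss$P <= 0 | ss$P > 1)) abort("sumstats P must be in (0, 1]")
  if (anyDuplicated(ss$SNP)) {
    warn("duplicate SNP ids in sumstats; keeping first occurrence")
    ss <- ss[!duplicated(ss$SNP), ]
  }
  ss
}

#' Write a sumstats tibble as tab-separated text
#' @param ss Sumstats tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  write.table(ss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Harmonize GWAS weights against a genotype panel
#'
#' Intersects a sumstats table with a genotype panel by SNP id, aligns the
#' effect to the panel's counted allele (flipping the sign when the effect
#' allele is the panel's other allele), then re-orients every entry so the
#' weight is non-negative — i.e. each SNP is coded to count the
#' risk-increasing allele. SNPs whose allele pairs cannot be reconciled are
#' dropped and tallied in the `n_mismatched` attribute.
#'
#' @param ss Sumstats tibble (columns SNP, A1, A2, BETA at minimum).
#' @param g A `genotype_data` object.
#' @param drop_palindromic Drop strand-ambiguous A/T and C/G SNPs. Off by
#'   default: with array-genotyped data matched directly to GWAS results no
#'   strand inference is involved.
#'
#' @return A weight table tibble: `id`, `counted_allele`, `other_allele`,
#'   `weight` (>= 0), `source`; attributes `n_mismatched`, `n_palindromic_dropped`.
#' @export
harmonize_weights <- function(ss, g, drop_palindromic = FALSE) {
  if (nrow(ss) == 0) abort("empty sumstats table")
  if (!inherits(g, "genotype_data")) abort("`g` must be a genotype_data.")
  sm <- g$snp_meta
  common <- intersect(ss$SNP, sm$id)
  if (length(common) == 0) {
    abort("no SNPs shared between the sumstats table and the genotype panel")
  }
  ssx <- ss[match(common, ss$SNP), ]
  smx <- sm[match(common, sm$id), ]
  n_pal <- 0L
  if (drop_palindromic) {
    pal <- paste0(ssx$A1, ssx$A2) %in% c("AT", "TA", "CG", "GC")
    n_pal <- sum(pal)
    ssx <- ssx[!pal, ]
    smx <- smx[!pal, ]
  }
  same <- ssx$A1 == smx$a1 & ssx$A2 == smx$a2
  flipped <- ssx$A1 == smx$a2 & ssx$A2 == smx$a1
  n_mismatch <- sum(!(same | flipped))
  keep <- same | flipped
  ssx <- ssx[keep, ]
  smx <- smx[keep, ]
  if (nrow(ssx) == 0) abort("no reconcilable SNPs after allele matching")
  # align effect to the panel's counted allele
  weight <- ifelse(ssx$A1 == smx$a1, ssx$BETA, -ssx$BETA)
  counted <- smx$a1
  other <- smx$a2
  # risk orientation: make every weight non-negative
  neg <- weight < 0
  weight[neg] <- -weight[neg]
  tmp <- counted[neg]
  counted[neg] <- other[neg]
  other[neg] <- tmp
  out <- tibble::tibble(
    id = ssx$SNP, counted_allele = counted, other_allele = other,
    weight = weight,
    source = attr(ss, "trait") %||% "trait"
  )
  attr(out, "n_mismatched") <- n_mismatch
  attr(out, "n_palindromic_dropped") <- n_pal
  out
}

#' Compute polygenic scores
#'
#' Raw score = sum over SNPs of `weight x dosage of the counted allele`,
#' with every matched SNP included — no LD trimming and no p-value
#' threshold. Missing dosages are mean-imputed as twice the counted-allele
#' frequency (`missing_policy = "mean_impute"`, the PLINK convention) or the
#' SNP is skipped for that individual (`"omit"`). Scores are normalized
#' within sample to z-scores.
#'
#' @param g A `genotype_data` object containing every SNP in `w`.
#' @param w Weight table from [harmonize_weights()] (or converted from
#'   latent weights via [as_weight_table()]).
#' @param missing_policy `"mean_impute"` or `"omit"`.
#'
#' @return A `pgs_result` tibble: `id`, `raw_score`, `z_score`,
#'   `n_snps_used`, `trait`.
#' @export
compute_pgs <- function(g, w, missing_policy = c("mean_impute", "omit")) {
  missing_policy <- match.arg(missing_policy)
  if (!inherits(g, "genotype_data")) abort("`g` must be a genotype_data.")
  idx <- match(w$id, g$snp_meta$id)
  if (anyNA(idx)) {
    abort(sprintf("%d weight SNPs absent from the genotype panel",
                  sum(is.na(idx))))
  }
  d <- g$dosage[, idx, drop = FALSE]
  sm <- g$snp_meta[idx, ]
  # orient dosages to the weight table's counted allele
  flip <- w$counted_allele == sm$a2
  bad <- !(flip | w$counted_allele == sm$a1)
  if (any(bad)) abort("weight counted_allele matches neither panel allele")
  d[, flip] <- 2L - d[, flip, drop = FALSE]
  storage.mode(d) <- "double"
  if (anyNA(d)) {
    if (missing_policy == "mean_impute") {
      af <- colMeans(d, na.rm = TRUE) / 2
      for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- 2 * af[j]
      n_used <- rep(nrow(w), nrow(d))
    } else {
      obs <- !is.na(d)
      n_used <- rowSums(obs)
      if (any(n_used == 0)) {
        abort("some individuals have zero usable SNPs under `omit`")
      }
      d[!obs] <- 0
    }
  } else {
    n_used <- rep(nrow(w), nrow(d))
  }
  raw <- as.vector(d %*% w$weight)
  tibble::new_tibble(
    tibble::tibble(
      id = g$sample_meta$id,
      raw_score = raw,
      z_score = normalize_pgs(raw),
      n_snps_used = as.integer(n_used),
      trait = w$source[1] %||% "trait"
    ),
    class = "pgs_result"
  )
}

#' Normalize scores within sample
#'
#' Centers and scales to sample mean 0, SD 1 (n - 1 denominator).
#'
#' @param raw Numeric vector of raw scores (length >= 2, non-constant).
#' @return The z-scored vector.
#' @export
#' @examples
#' normalize_pgs(c(1, 2, 3))
normalize_pgs <- function(raw) {
  if (length(raw) < 2) abort("need at least 2 scores to normalize")
  s <- sd(raw)
  if (!is.finite(s) || s == 0) abort("scores have zero variance; cannot normalize")
  (raw - mean(raw)) / s
}

#' Write / read a weight table
#' @param w Weight-table tibble.
#' @param path File path.
#' @return `path` (write) or the weight tibble (read).
#' @export
write_weight_table <- function(w, path) {
  write.table(w, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_table
#' @export
read_weight_table <- function(path) {
  tibble::as_tibble(
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  )
}
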