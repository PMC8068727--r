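#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on observed genotype counts, by enumeration of all
#' possible heterozygote counts conditional on the allele counts
#' (Wigginton-style). Preferred over the chi-square approximation because
#' the screening threshold (1e-4) sits far in the tail, where the
#' approximation is poor at moderate counts.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (hom counted, het, hom other).
#' @return The exact p-value (probability of a heterozygote count at most
#'   as likely as the observed one).
#' @export
#' @examples
#' hwe_exact_test(50, 0, 50) # extreme heterozygote deficit
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) abort("genotype counts must be >= 0")
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab # count of the rarer allele handled below
  if (n_a > n) { # work with the minor allele
    n_a <- 2 * n - n_a
  }
  hets <- seq.int(n_a %% 2, n_a, by = 2)
  # log P(het = h | allele counts) up to a constant
  lp <- vapply(hets, function(h) {
    hom_a <- (n_a - h) / 2
    hom_b <- n - hom_a - h
    h * log(2) - lfactorial(hom_a) - lfactorial(h) - lfactorial(hom_b)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  sum(pr[pr <= obs + 1e-12])
}

#' Genotype quality control
#'
#' Applies the three screening stages in a fixed order: (1) individuals with
#' missing call rate above `ind_missing_max` are removed; (2) SNPs with call
#' rate below `snp_callrate_min` (computed on the retained individuals) are
#' removed; (3) SNPs failing the exact Hardy-Weinberg test at `hwe_alpha`
#' are removed. The order matters because call-rate and HWE statistics
#' depend on the retained individual set; it is recorded in the report.
#'
#' @param g A `genotype_data` object.
#' @param ind_missing_max Maximum tolerated per-individual missing rate.
#' @param snp_callrate_min Minimum tolerated per-SNP call rate.
#' @param hwe_alpha HWE exact-test significance threshold.
#'
#' @return A list with `genotypes` (filtered `genotype_data`) and `report`
#'   (a `qc_report`: removal counts per stage plus the thresholds used).
#' @export
qc_filter <- function(g, ind_missing_max = 0.02, snp_callrate_min = 0.98,
                      hwe_alpha = 1e-4) {
  if (!inherits(g, "genotype_data")) abort("`g` must be a genotype_data.")
  if (nrow(g$dosage) == 0 || ncol(g$dosage) == 0) abort("`g` is empty")
  d <- g$dosage

  ind_miss <- rowMeans(is.na(d))
  keep_ind <- ind_miss <= ind_missing_max
  if (!any(keep_ind)) {
    abort("QC individual-missingness stage removed every individual")
  }
  d <- d[keep_ind, , drop = FALSE]

  callrate <- colMeans(!is.na(d))
  keep_call <- callrate >= snp_callrate_min
  if (!any(keep_call)) abort("QC call-rate stage removed every SNP")
  d2 <- d[, keep_call, drop = FALSE]

  hwe_p <- vapply(seq_len(ncol(d2)), function(j) {
    x <- d2[, j]
    hwe_exact_test(sum(x == 2L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
                   sum(x == 0L, na.rm = TRUE))
  }, numeric(1))
  keep_hwe <- hwe_p >= hwe_alpha
  if (!any(keep_hwe)) abort("QC HWE stage removed every SNP")

  keep_snps <- colnames(d2)[keep_hwe]
  out <- new_genotype_data(
    d2[, keep_hwe, drop = FALSE],
    g$snp_meta[match(keep_snps, g$snp_meta$id), , drop = FALSE],
    g$sample_meta[keep_ind, , drop = FALSE]
  )
  report <- structure(
    list(
      n_individuals_removed = sum(!keep_ind),
      n_snps_removed_callrate = sum(!keep_call),
      n_snps_removed_hwe = sum(!keep_hwe),
      thresholds = list(
        ind_missing_max = ind_missing_max,
        snp_callrate_min = snp_callrate_min,
        hwe_alpha = hwe_alpha
      ),
      stage_order = c("individual_missingness", "snp_callrate", "snp_hwe")
    ),
    class = "qc_report"
  )
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  individuals removed (missing > %g): %d\n",
              x$thresholds$ind_missing_max, x$n_individuals_removed))
  cat(sprintf("  SNPs removed (call rate < %g): %d\n",
              x$thresholds$snp_callrate_min, x$n_snps_removed_callrate))
  cat(sprintf("  SNPs removed (HWE p < %g): %d\n",
              x$thresholds$hwe_alpha, x$n_snps_removed_hwe))
  invisible(x)
}

#' @rdname tidy_latentpgs
#' @export
tidy.qc_report <- function(x, ...) {
  tibble::tibble(
    stage = c("individual_missingness", "snp_callrate", "snp_hwe"),
    removed = c(x$n_individuals_removed, x$n_snps_removed_callrate,
                x$n_snps_removed_hwe),
    threshold = c(x$thresholds$ind_missing_max, x$thresholds$snp_callrate_min,
                  x$thresholds$hwe_alpha)
  )
}
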