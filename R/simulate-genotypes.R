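#' Specify a synthetic SNP panel
#'
#' Describes the genotyping panel emulated by [simulate_genotypes()]: how many
#' SNPs, how they are grouped into independent LD blocks, the latent
#' (copula-scale) correlation of SNPs within a block, and the range minor
#' allele frequencies are drawn from.
#'
#' @param n_snps Number of SNPs on the panel.
#' @param n_blocks Number of independent LD blocks; SNPs are split into
#'   contiguous blocks of near-equal size.
#' @param within_block_corr Correlation of the latent Gaussian haplotype
#'   variables for SNPs in the same block, in `[0, 1)`. `0` gives linkage
#'   equilibrium.
#' @param maf_range Length-2 numeric; per-SNP minor allele frequencies are
#'   drawn uniformly from this interval, each endpoint in `(0, 0.5]`.
#'   Equal endpoints fix the MAF.
#' @param missing_rate Fraction of dosages set missing completely at random.
#' @param meta_seed Seed for the panel's own properties (MAFs, allele
#'   labels). Fixed per panel — not per draw — so every cohort, reference
#'   sample or target sample simulated from one panel shares the same
#'   population allele frequencies and LD structure.
#'
#' @return An object of class `snp_panel_spec`.
#' @export
#' @examples
#' snp_panel_spec(n_snps = 100, n_blocks = 10, within_block_corr = 0.7)
snp_panel_spec <- function(n_snps, n_blocks = 1L, within_block_corr = 0,
                           maf_range = c(0.05, 0.5), missing_rate = 0,
                           meta_seed = 1861L) {
  stop_if_not_count(n_snps, "n_snps")
  stop_if_not_count(n_blocks, "n_blocks")
  if (n_blocks > n_snps) abort("`n_blocks` cannot exceed `n_snps`.")
  if (!is.numeric(within_block_corr) || length(within_block_corr) != 1L ||
      within_block_corr < 0 || within_block_corr >= 1) {
    abort("`within_block_corr` must be a single value in [0, 1).")
  }
  if (length(maf_range) != 2L || any(maf_range < 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be (lower, upper) with 0 <= lower <= upper <= 0.5.")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must be in [0, 1).")
  }
  structure(
    list(
      n_snps = as.integer(n_snps), n_blocks = as.integer(n_blocks),
      within_block_corr = within_block_corr,
      maf_range = as.numeric(maf_range), missing_rate = missing_rate,
      meta_seed = as.integer(meta_seed)
    ),
    class = "snp_panel_spec"
  )
}

# contiguous blocks with random boundaries (deterministic per panel), so
# block sizes — and hence LD scores — vary across the panel as they do in
# real genomes
panel_blocks <- function(panel) {
  if (panel$n_blocks == 1L) return(rep(1L, panel$n_snps))
  cuts <- with_seed(
    panel$meta_seed + 1L,
    sort(sample.int(panel$n_snps - 1L, panel$n_blocks - 1L))
  )
  sizes <- diff(c(0L, cuts, panel$n_snps))
  rep(seq_len(panel$n_blocks), sizes)
}

# draw per-SNP MAFs and allele labels for a panel (deterministic given seed)
panel_snp_meta <- function(panel, seed) {
  with_seed(seed, {
    maf <- runif(panel$n_snps, panel$maf_range[1], panel$maf_range[2])
    pairs <- rbind(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"))
    pick <- pairs[sample.int(4L, panel$n_snps, replace = TRUE), , drop = FALSE]
    tibble::tibble(
      id = sprintf("rs%06d", seq_len(panel$n_snps)),
      chr = panel_blocks(panel),
      pos = seq_len(panel$n_snps) * 1000L,
      a1 = pick[, 1], a2 = pick[, 2],
      maf = maf, block = panel_blocks(panel)
    )
  })
}

# core sampler: dosages for one block via the Gaussian copula.
# Two latent standard normals per individual (one per haplotype copy), each
# equicorrelated across the block's SNPs at `rho`; an allele is carried when
# its latent normal falls below the MAF quantile, and the two copies sum to
# the dosage.
sample_block_dosages <- function(n, maf, rho) {
  m <- length(maf)
  thr <- qnorm(maf)
  thr_full <- rep(thr, each = n)
  d <- matrix(0L, n, m)
  for (copy in 1:2) {
    if (rho > 0) {
      shared <- rnorm(n)
      z <- sqrt(rho) * shared + sqrt(1 - rho) * matrix(rnorm(n * m), n, m)
    } else {
      z <- matrix(rnorm(n * m), n, m)
    }
    d <- d + (z < thr_full)
  }
  d
}

#' Simulate diploid genotypes with block LD
#'
#' Draws an individuals-by-SNPs dosage matrix from a Gaussian copula: each
#' haplotype copy of each individual has a latent standard normal per SNP,
#' equicorrelated within LD blocks, and carries the counted allele when the
#' latent variable falls below the allele-frequency quantile. Dosage is the
#' sum over the two copies, so each SNP is marginally binomial(2, maf) and
#' blocks are mutually independent.
#'
#' @param n_individuals Number of individuals (at least 2).
#' @param panel A [snp_panel_spec()].
#' @param seed Integer seed; identical inputs and seed give identical output.
#'
#' @return A `genotype_data` object: list with `dosage` (integer matrix,
#'   `NA` for missing), `snp_meta` (tibble: id, chr, pos, a1 = counted allele,
#'   a2, maf) and `sample_meta` (tibble: id, group).
#' @export
#' @examples
#' g <- simulate_genotypes(50, snp_panel_spec(20, 4, 0.6), seed = 1)
#' dim(g$dosage)
simulate_genotypes <- function(n_individuals, panel, seed) {
  stop_if_not_count(n_individuals, "n_individuals")
  if (n_individuals < 2) abort("`n_individuals` must be at least 2.")
  if (!inherits(panel, "snp_panel_spec")) abort("`panel` must be a snp_panel_spec.")
  seeds <- derive_seeds(seed, 2L + panel$n_blocks)
  meta <- panel_snp_meta(panel, panel$meta_seed)
  blocks <- split(seq_len(panel$n_snps), meta$block)
  dosage <- matrix(0L, n_individuals, panel$n_snps)
  for (b in seq_along(blocks)) {
    j <- blocks[[b]]
    dosage[, j] <- with_seed(
      seeds[2L + b],
      sample_block_dosages(n_individuals, meta$maf[j], panel$within_block_corr)
    )
  }
  if (panel$missing_rate > 0) {
    dosage[with_seed(
      seeds[2],
      which(runif(length(dosage)) < panel$missing_rate)
    )] <- NA_integer_
  }
  colnames(dosage) <- meta$id
  sample_meta <- tibble::tibble(
    id = sprintf("id%06d", seq_len(n_individuals)),
    group = "synthetic"
  )
  rownames(dosage) <- sample_meta$id
  new_genotype_data(dosage, dplyr::select(meta, -"block"), sample_meta)
}

new_genotype_data <- function(dosage, snp_meta, sample_meta) {
  stopifnot(ncol(dosage) == nrow(snp_meta), nrow(dosage) == nrow(sample_meta))
  if (anyDuplicated(snp_meta$id)) abort("duplicate SNP ids in genotype data")
  if (anyDuplicated(sample_meta$id)) abort("duplicate sample ids in genotype data")
  structure(
    list(dosage = dosage, snp_meta = snp_meta, sample_meta = sample_meta),
    class = "genotype_data"
  )
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf(
    "<genotype_data> %d individuals x %d SNPs (%.2f%% missing)\n",
    nrow(x$dosage), ncol(x$dosage), 100 * mean(is.na(x$dosage))
  ))
  if (any(grepl("^PC", names(x$sample_meta)))) {
    cat("  ancestry PCs attached:",
        sum(grepl("^PC", names(x$sample_meta))), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_data <- function(x) dim(x$dosage)
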