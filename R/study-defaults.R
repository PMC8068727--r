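#' Default synthetic study conditions
#'
#' Frozen generating models used throughout the package's tests and
#' examples. The phenotype truth mirrors the reported psychopathology
#' structure in older adults: six indicators (negative affect, anxiety,
#' depressive symptoms; impulsivity, trait anger, state anger), strong
#' internalizing loadings (0.88, 0.80, 0.63), moderate externalizing
#' loadings (0.50, 0.42, 0.33), an inter-factor correlation of 0.82, and a
#' small nuisance dimension that neither fitted model represents. The
#' nuisance scale and externalizing loadings were calibrated so that the
#' population discrepancies of the one- and two-factor models at n = 3002
#' match the reported fit levels (population RMSEA about 0.047 and 0.041)
#' — the regime in which both models fit acceptably, their delta-fit
#' difference is below the depreciation thresholds, and the factors are
#' not distinct. The genetic truth mirrors a seven-trait two-factor
#' architecture (three internalizing, four externalizing GWAS) with a
#' genetic factor correlation of 0.64, SNP heritabilities in the 0.09-0.22
#' range, and heavily overlapping discovery cohorts.
#'
#' @param r_factor Phenotypic inter-factor correlation.
#' @return A [pheno_truth()] / [genetic_truth()].
#' @export
default_phenotype_truth <- function(r_factor = 0.82) {
  ind <- c("neg_affect", "anxiety", "depress",
           "impulsivity", "trait_anger", "state_anger")
  lam <- cbind(c(0.88, 0.80, 0.63, 0, 0, 0),
               c(0, 0, 0, 0.50, 0.42, 0.33))
  pheno_truth(ind, lam,
              factor_corr = matrix(c(1, r_factor, r_factor, 1), 2),
              nuisance_loadings = 0.8 * c(0.2, 0.1, -0.25, 0.3, -0.2, 0.1))
}

#' @rdname default_phenotype_truth
#' @param n_per_trait GWAS cohort size per trait.
#' @param overlap_frac Fraction of each pair of cohorts that is shared
#'   individuals (1 = one fully shared cohort, the regime behind strong
#'   cross-trait LDSC intercepts).
#' @param factor_corr_genetic Genetic factor correlation.
#' @export
default_genetic_truth <- function(n_per_trait = 12000,
                                  overlap_frac = 1,
                                  factor_corr_genetic = 0.64) {
  traits <- c("neuroticism", "anxiety_dx", "mdd",
              "alcohol_dep", "adhd", "cannabis", "antisocial")
  std_load <- cbind(c(0.70, 0.88, 0.95, 0, 0, 0, 0),
                    c(0, 0, 0, 0.81, 0.60, 0.50, 0.79))
  h2 <- c(0.15, 0.12, 0.15, 0.10, 0.22, 0.11, 0.09)
  n <- rep(n_per_trait, 7)
  ov <- matrix(round(overlap_frac * n_per_trait), 7, 7)
  diag(ov) <- n
  genetic_truth(
    traits,
    loadings = std_load * sqrt(h2),
    factor_corr = matrix(c(1, factor_corr_genetic,
                           factor_corr_genetic, 1), 2),
    total_h2 = h2,
    n_per_trait = n,
    pairwise_overlap = ov,
    env_corr = diag(7) * 0.5 + 0.5
  )
}

#' @rdname default_phenotype_truth
#' @param n_snps,n_blocks,within_block_corr Panel dimensions; see
#'   [snp_panel_spec()].
#' @export
default_snp_panel <- function(n_snps = 2000L, n_blocks = 100L,
                              within_block_corr = 0.6) {
  snp_panel_spec(n_snps, n_blocks, within_block_corr,
                 maf_range = c(0.05, 0.5))
}

#' @rdname default_phenotype_truth
#' @details `pleiotropic_genetic_truth()` is the single-factor variant in
#'   which essentially all SNP effects act through one shared genetic
#'   factor (standardized loadings 0.85-0.95, so trait-specific genetic
#'   variance is near zero). This is the regime in which a latent-factor
#'   polygenic score aggregates independent GWAS noise across traits and
#'   outperforms every single-trait score.
#' @export
pleiotropic_genetic_truth <- function(n_per_trait = 6000) {
  traits <- c("neuroticism", "anxiety_dx", "mdd",
              "alcohol_dep", "adhd", "cannabis", "antisocial")
  h2 <- c(0.15, 0.12, 0.15, 0.10, 0.22, 0.11, 0.09)
  stdl <- c(0.92, 0.90, 0.95, 0.85, 0.88, 0.85, 0.90)
  n <- rep(n_per_trait, 7)
  # one cohort phenotyped for all seven traits; environmental residuals
  # independent across traits, so GWAS estimation errors stay independent
  ov <- matrix(n_per_trait, 7, 7)
  genetic_truth(
    traits, matrix(stdl * sqrt(h2), 7, 1), total_h2 = h2,
    n_per_trait = n, pairwise_overlap = ov
  )
}
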