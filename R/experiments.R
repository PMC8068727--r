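# Calibration experiments: self-contained study-condition runs used by the
# acceptance checks and reproducible from scripts/acceptance.R. Each takes
# a seed and returns the measured quantities; none reads external data.

#' Calibration experiments for the inference chain
#'
#' Each experiment runs a fixed study condition end to end and measures a
#' recovery or decision quantity with known ground truth. They back the
#' package's acceptance checks and are reproducible from a single seed.
#'
#' `experiment_cfa_oracle()` fits just-identified 3-indicator one-factor
#' models to random factor-compatible correlation matrices and returns the
#' maximum absolute deviation of the standardized loadings from the
#' closed form `lambda_1 = sqrt(s12 s13 / s23)` (and permutations).
#'
#' @param n_matrices Number of random matrices.
#' @param seed Master seed.
#' @return `experiment_cfa_oracle`: list with `max_error` and `n`.
#' @export
experiment_cfa_oracle <- function(n_matrices = 100, seed = 1) {
  seeds <- derive_seeds(seed, n_matrices)
  worst <- 0
  spec <- factor_model_spec(c("a", "b", "c"))
  for (r in seq_len(n_matrices)) {
    s <- with_seed(seeds[r], {
      l <- runif(3, 0.3, 0.95)
      s0 <- tcrossprod(l)
      diag(s0) <- 1
      s0
    })
    y <- exact_cov_sample(200, s, seeds[r] + 1)
    d <- as.data.frame(y)
    names(d) <- c("a", "b", "c")
    fit <- fit_cfa(d, spec, estimator = "ml")
    std <- standardized_solution(fit)
    lam <- std$std_estimate[std$mat == "lambda"][
      match(c("a", "b", "c"), std$indicator[std$mat == "lambda"])
    ]
    s12 <- cov(d)[1, 2]
    s13 <- cov(d)[1, 3]
    s23 <- cov(d)[2, 3]
    closed <- c(sqrt(s12 * s13 / s23), sqrt(s12 * s23 / s13),
                sqrt(s13 * s23 / s12))
    worst <- max(worst, max(abs(abs(lam) - closed)))
  }
  list(max_error = worst, n = n_matrices)
}

# data whose sample covariance equals `sigma` exactly
exact_cov_sample <- function(n, sigma, seed) {
  p <- ncol(sigma)
  x <- with_seed(seed, matrix(rnorm(n * p), n, p))
  x <- scale(x, center = TRUE, scale = FALSE)
  x <- x %*% solve(chol(cov(x)))
  x %*% chol(sigma)
}

#' @rdname experiment_cfa_oracle
#' @details `experiment_invariance_calibration()` simulates two groups from
#'   the default phenotype model, either identical (`intercept_shift = 0`)
#'   or with a planted intercept offset, runs the invariance ladder and
#'   returns per-level outcome rates.
#' @param n_reps Replicates.
#' @param n_per_group Individuals per group.
#' @param intercept_shift Intercept offset (in indicator SD units) planted
#'   in the second group.
#' @export
experiment_invariance_calibration <- function(n_reps = 100,
                                              n_per_group = 1000,
                                              intercept_shift = 0,
                                              seed = 1) {
  ind <- c("neg_affect", "anxiety", "depress",
           "impulsivity", "trait_anger", "state_anger")
  lam <- c(0.88, 0.80, 0.63, 0.38, 0.31, 0.28)
  tr <- pheno_truth(ind, lam,
                    intercepts_by_group = rbind(rep(0, 6),
                                                rep(intercept_shift, 6)))
  spec <- factor_model_spec(ind)
  seeds <- derive_seeds(seed, n_reps)
  residual_attained <- scalar_depreciated <- metric_attained <- 0L
  for (r in seq_len(n_reps)) {
    d <- simulate_phenotype_panel(2 * n_per_group, tr,
                                  rep(c("g1", "g2"), each = n_per_group),
                                  seed = seeds[r])
    lad <- invariance_ladder(d, spec, "group")
    residual_attained <- residual_attained +
      (lad$highest_level_attained == "residual")
    metric_attained <- metric_attained +
      (lad$highest_level_attained %in% c("metric", "scalar", "residual"))
    scalar_depreciated <- scalar_depreciated +
      (lad$verdicts$scalar$verdict == "depreciated")
  }
  list(residual_attained_rate = residual_attained / n_reps,
       metric_attained_rate = metric_attained / n_reps,
       scalar_depreciated_rate = scalar_depreciated / n_reps,
       n = n_reps)
}

#' @rdname experiment_cfa_oracle
#' @details `experiment_ldsc_recovery()` simulates, per replicate, three
#'   GWAS cohorts of `n_ind` individuals on a `n_snps` panel: traits A and
#'   B genetically correlated at 0.64 with half their samples shared, and
#'   trait C independent and disjoint. It measures jackknife-CI coverage of
#'   the SNP heritabilities and of the A-B genetic correlation, plus the
#'   cross-trait intercepts for the overlapping and disjoint pairs.
#' @param n_snps,n_ind Simulation scale.
#' @export
experiment_ldsc_recovery <- function(n_reps = 20, n_snps = 5000,
                                     n_ind = 10000, seed = 1) {
  h2 <- 0.4
  rg <- 0.64
  lam <- rbind(c(sqrt(h2), 0, 0),
               c(rg * sqrt(h2), sqrt(h2 * (1 - rg^2)), 0),
               c(0, 0, sqrt(h2)))
  ov <- matrix(0, 3, 3)
  ov[1, 2] <- ov[2, 1] <- n_ind / 2
  env <- diag(3)
  env[1, 2] <- env[2, 1] <- 0.4
  truth <- genetic_truth(c("a", "b", "c"), lam, total_h2 = rep(h2, 3),
                         n_per_trait = rep(n_ind, 3),
                         pairwise_overlap = ov, env_corr = env)
  # many short LD blocks: the block jackknife needs a large number of
  # independent LD units for calibrated standard errors, and intercept
  # identification benefits from plenty of low-LD SNPs
  panel <- snp_panel_spec(n_snps, max(50L, n_snps %/% 10L), 0.7,
                          maf_range = c(0.05, 0.5))
  ref <- simulate_genotypes(3000, panel, seed = seed + 491)
  ld <- compute_ld_scores(ref, window_snps = min(150L, n_snps))
  seeds <- derive_seeds(seed, n_reps)
  cover_h2 <- cover_rg <- 0L
  checks_h2 <- 0L
  int_overlap <- int_null <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    gw <- simulate_multitrait_gwas(truth, panel, seed = seeds[r])
    # jackknife blocks must span several LD blocks to be near-independent;
    # the simple 1/L2 weights avoid the small-sample slope bias of
    # data-estimated inverse-variance weights at this SNP count
    gcv <- build_genetic_cov(gw$sumstats, ld, n_blocks = 25L,
                             weights = "mixed")
    qt <- stats::qt(0.975, gcv$n_blocks - 1)
    for (i in 1:3) {
      est <- diag(gcv$S_raw)[i]
      se <- sqrt(diag(gcv$V)[c(1, 4, 6)][i])
      cover_h2 <- cover_h2 + (abs(est - h2) <= qt * se)
      checks_h2 <- checks_h2 + 1L
    }
    # jackknife the genetic correlation directly over the shared blocks
    rg_hat <- gcv$S_raw[1, 2] / sqrt(gcv$S_raw[1, 1] * gcv$S_raw[2, 2])
    rg_loo <- gcv$loo[, 2] / sqrt(pmax(gcv$loo[, 1] * gcv$loo[, 4], 1e-12))
    bb <- length(rg_loo)
    rg_se <- sqrt((bb - 1) / bb * sum((rg_loo - mean(rg_loo))^2))
    cover_rg <- cover_rg + (abs(rg_hat - rg) <= qt * rg_se)
    int_overlap[r] <- gcv$intercepts[1, 2]
    int_null[r] <- gcv$intercepts[1, 3]
  }
  d_paired <- int_overlap - int_null
  list(h2_coverage = as.numeric(cover_h2 / checks_h2),
       rg_coverage = as.numeric(cover_rg / n_reps),
       pooled_coverage = as.numeric((cover_h2 + cover_rg) /
                                      (checks_h2 + n_reps)),
       mean_intercept_overlap = mean(int_overlap),
       mean_intercept_null = mean(int_null),
       se_intercept_overlap = sd(int_overlap) / sqrt(n_reps),
       se_intercept_null = sd(int_null) / sqrt(n_reps),
       paired_intercept_t = mean(d_paired) /
         (sd(d_paired) / sqrt(n_reps)),
       n = n_reps)
}

#' @rdname experiment_cfa_oracle
#' @details `experiment_gsem_recovery()` simulates seven GWAS from the
#'   default two-factor genetic truth (factor correlation 0.64, fully
#'   overlapping cohorts), assembles (S, V), fits one- and two-factor
#'   models and measures parameter coverage and the model-preference
#'   pattern (two-factor wins on delta chi-square, delta CFI and AIC).
#' @export
experiment_gsem_recovery <- function(n_reps = 20, seed = 1) {
  truth <- default_genetic_truth(n_per_trait = 12000)
  panel <- default_snp_panel(3500, 150)
  traits <- truth$trait_names
  spec1 <- factor_model_spec(traits, list(GEN = traits))
  spec2 <- factor_model_spec(traits,
                             list(INT = traits[1:3], EXT = traits[4:7]))
  ref <- simulate_genotypes(1500, panel, seed = seed + 271)
  ld <- compute_ld_scores(ref, window_snps = 200L)
  seeds <- derive_seeds(seed, n_reps)
  prefer_two <- 0L
  covered <- total <- 0L
  corr_covered <- 0L
  for (r in seq_len(n_reps)) {
    gw <- simulate_multitrait_gwas(truth, panel, seed = seeds[r])
    gcv <- build_genetic_cov(gw$sumstats, ld, n_blocks = 40L)
    f1 <- fit_gsem(gcv, spec1)
    f2 <- fit_gsem(gcv, spec2)
    # a Heywood constraint triggered in either model is applied to both,
    # so the pair stays nested with delta-df 1 (the same handling the
    # reported genetic models used for their smallest-residual trait)
    fixed <- union(f1$heywood_fixed, f2$heywood_fixed)
    if (length(fixed)) {
      fx <- setNames(rep(0, length(fixed)), fixed)
      s1 <- spec1
      s1$fixed_residuals <- fx
      s2 <- spec2
      s2$fixed_residuals <- fx
      f1 <- fit_gsem(gcv, s1)
      f2 <- fit_gsem(gcv, s2)
    }
    # loadings coverage in the unstandardized (heritability) metric
    pt <- f2$ptab
    lam_rows <- which(pt$mat == "lambda" & pt$free > 0)
    for (rr in lam_rows) {
      est <- f2$theta[pt$free[rr]]
      se <- f2$se[pt$free[rr]]
      tv <- truth$loadings[pt$row[rr], pt$col[rr]]
      if (is.finite(se) && se > 0) {
        covered <- covered + (abs(abs(est) - tv) <= 1.96 * se)
        total <- total + 1L
      }
    }
    psi_row <- which(pt$mat == "psi" & pt$row != pt$col & pt$free > 0)
    est_r <- f2$theta[pt$free[psi_row]]
    se_r <- f2$se[pt$free[psi_row]]
    corr_covered <- corr_covered +
      (abs(abs(est_r) - truth$factor_corr[1, 2]) <= 1.96 * se_r)
    cmp <- compare_gsem(free = f2, restricted = f1)
    # two-factor preferred: positive scaled difference with an AIC margin
    # and no CFI loss (delta_cfi is restricted minus free, so <= 0 means
    # the one-factor restriction does not improve CFI)
    prefer_two <- prefer_two +
      (cmp$delta_chi2 > 0 && cmp$delta_cfi <= 0 && cmp$delta_aic > 0)
  }
  list(loading_coverage = covered / total,
       factor_corr_coverage = corr_covered / n_reps,
       pooled_coverage = (covered + corr_covered) / (total + n_reps),
       prefer_two_rate = prefer_two / n_reps,
       n = n_reps)
}

#' @rdname experiment_cfa_oracle
#' @details `experiment_latent_advantage()` runs the full chain (GWAS
#'   simulation under the pleiotropic one-factor truth, LDSC, genetic
#'   factor model, latent SNP weights, polygenic scoring in an independent
#'   target sample whose phenotypic general factor is partly the true
#'   genetic factor value) and compares the mean incremental R-squared of
#'   the latent one-factor score against every single-trait score.
#' @export
experiment_latent_advantage <- function(n_reps = 50, seed = 1) {
  traits <- pleiotropic_genetic_truth()$trait_names
  ind <- c("neg_affect", "anxiety", "depress",
           "impulsivity", "trait_anger", "state_anger")
  seeds <- derive_seeds(seed, n_reps)
  acc <- NULL
  for (r in seq_len(n_reps)) {
    cfg <- study_config(
      synthetic = list(
        genetic = list(truth = pleiotropic_genetic_truth(),
                       panel = default_snp_panel(1200, 60)),
        target = list(n = 1500),
        phenotype = list(truth = default_phenotype_truth(), n = 1500,
                         coupling = list(factor = 1, h2 = 0.25))
      ),
      models = list(
        pheno_one = factor_model_spec(ind),
        genetic_one = factor_model_spec(traits, list(GEN = traits))
      ),
      seed = seeds[r]
    )
    a <- run_study(cfg)$associations
    acc <- rbind(acc, setNames(a$r2_incremental, a$predictor))
  }
  means <- colMeans(acc)
  singles <- means[paste0("pgs_", traits)]
  list(mean_r2_latent = unname(means["pgs_GEN"]),
       best_single = unname(max(singles)),
       best_single_name = names(singles)[which.max(singles)],
       mean_r2_singles = as.list(singles),
       latent_beats_all = unname(means["pgs_GEN"] > max(singles)),
       n = n_reps)
}

#' @rdname experiment_cfa_oracle
#' @details `experiment_pipeline_decision()` runs the phenotype-only
#'   pipeline on data from the default two-factor truth (inter-factor
#'   correlation 0.82) and returns how often the one-factor model is
#'   accepted, together with the rate at which the factor-distinctness
#'   alert fires.
#' @param n_individuals Phenotype panel size per replicate.
#' @export
experiment_pipeline_decision <- function(n_reps = 50, n_individuals = 6003,
                                         seed = 1) {
  ind <- c("neg_affect", "anxiety", "depress",
           "impulsivity", "trait_anger", "state_anger")
  seeds <- derive_seeds(seed, n_reps)
  one <- alert <- 0L
  for (r in seq_len(n_reps)) {
    cfg <- study_config(
      synthetic = list(phenotype = list(truth = default_phenotype_truth(),
                                        n = n_individuals)),
      models = list(
        pheno_one = factor_model_spec(ind),
        pheno_two = factor_model_spec(ind, list(INT = ind[1:3],
                                                EXT = ind[4:6]))
      ),
      seed = seeds[r]
    )
    rep_ <- run_study(cfg)
    one <- one + (rep_$accepted_model == "one_factor")
    alert <- alert + isTRUE(rep_$model_comparison$corr_alert)
  }
  list(one_factor_rate = one / n_reps,
       alert_rate = alert / n_reps,
       n = n_reps)
}
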