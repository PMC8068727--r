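#' Specify the generating genetic factor model for simulated GWAS
#'
#' Defines the latent genetic architecture that [simulate_multitrait_gwas()]
#' draws per-SNP effects from: trait loadings on one or more genetic factors,
#' factor correlations, per-trait total SNP heritability, cohort sizes, and
#' pairwise sample overlap between cohorts (the mechanism behind non-zero
#' cross-trait LD-score regression intercepts).
#'
#' Residual (trait-specific) genetic variance is derived as
#' `total_h2 - diag(L Phi L')` and must be non-negative; the implied genetic
#' correlation matrix must be positive semi-definite.
#'
#' @param trait_names Character vector of trait names.
#' @param loadings Numeric matrix (traits x factors) of genetic factor
#'   loadings on the heritability scale, or a vector for a single factor.
#' @param factor_corr Factor correlation matrix (default identity).
#' @param total_h2 Per-trait total SNP heritability in `[0, 1]`.
#' @param n_per_trait Per-trait GWAS cohort size.
#' @param pairwise_overlap Symmetric matrix of shared-sample counts between
#'   cohorts; diagonal is ignored. Default 0 (disjoint cohorts).
#' @param env_corr Correlation of the environmental (non-genetic) residuals
#'   across traits for individuals present in several cohorts; identity by
#'   default. Setting an off-diagonal to 1 with identical genetic rows makes
#'   two traits literal copies of one phenotype.
#'
#' @return An object of class `genetic_truth` with derived `residual_h2`
#'   and the generating genetic covariance `s_true` (standardized scale).
#' @export
genetic_truth <- function(trait_names, loadings, factor_corr = NULL,
                          total_h2, n_per_trait, pairwise_overlap = NULL,
                          env_corr = NULL) {
  t_n <- length(trait_names)
  if (is.vector(loadings)) loadings <- matrix(loadings, ncol = 1L)
  if (nrow(loadings) != t_n) abort("`loadings` must have one row per trait.")
  k <- ncol(loadings)
  factor_corr <- factor_corr %||% diag(k)
  if (!isTRUE(all.equal(factor_corr, t(factor_corr))) ||
      any(abs(diag(factor_corr) - 1) > 1e-8)) {
    abort("`factor_corr` must be a symmetric correlation matrix.")
  }
  if (any(total_h2 < 0 | total_h2 > 1) || length(total_h2) != t_n) {
    abort("`total_h2` must be per-trait values in [0, 1].")
  }
  if (length(n_per_trait) != t_n || any(n_per_trait < 2)) {
    abort("`n_per_trait` must give a cohort size (>= 2) per trait.")
  }
  common <- loadings %*% factor_corr %*% t(loadings)
  residual_h2 <- total_h2 - diag(common)
  if (any(residual_h2 < -1e-8)) {
    abort(paste0(
      "factor model implies more common genetic variance than `total_h2` for ",
      paste(trait_names[residual_h2 < -1e-8], collapse = ", ")
    ))
  }
  residual_h2 <- pmax(residual_h2, 0)
  s_true <- common + diag(residual_h2, t_n)
  pos <- total_h2 > 0
  if (any(pos)) {
    r_imp <- stats::cov2cor(s_true[pos, pos, drop = FALSE])
    if (min(eigen(r_imp, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      abort("implied genetic correlation matrix is not positive semi-definite")
    }
  }
  pairwise_overlap <- pairwise_overlap %||% matrix(0, t_n, t_n)
  if (any(pairwise_overlap != t(pairwise_overlap))) {
    abort("`pairwise_overlap` must be symmetric.")
  }
  diag(pairwise_overlap) <- n_per_trait
  lim <- outer(n_per_trait, n_per_trait, pmin)
  if (any(pairwise_overlap > lim)) {
    abort("overlap cannot exceed the smaller cohort size of a pair.")
  }
  env_corr <- env_corr %||% diag(t_n)
  dimnames(loadings) <- list(trait_names, paste0("F", seq_len(k)))
  dimnames(s_true) <- list(trait_names, trait_names)
  structure(
    list(
      trait_names = trait_names, loadings = loadings,
      factor_corr = factor_corr, total_h2 = total_h2,
      residual_h2 = residual_h2, n_per_trait = n_per_trait,
      pairwise_overlap = pairwise_overlap, env_corr = env_corr,
      s_true = s_true
    ),
    class = "genetic_truth"
  )
}

# Cohort membership as contiguous index intervals in one individual pool.
# Interval layout realizes disjoint, nested and chained pairwise overlap
# patterns exactly; the realized overlap matrix is returned and checked.
allocate_cohorts <- function(truth) {
  t_n <- length(truth$trait_names)
  n <- truth$n_per_trait
  ov <- truth$pairwise_overlap
  start <- integer(t_n)
  start[1] <- 1L
  if (t_n > 1) {
    for (i in 2:t_n) {
      # place relative to the earlier cohort it overlaps most with
      prev <- 1:(i - 1)
      j <- prev[which.max(ov[i, prev])]
      o <- ov[i, j]
      if (o == 0) {
        start[i] <- max(start[prev] + n[prev]) # fresh individuals
      } else {
        start[i] <- start[j] + n[j] - o
      }
    }
  }
  idx <- lapply(seq_len(t_n), function(i) start[i]:(start[i] + n[i] - 1L))
  realized <- outer(seq_len(t_n), seq_len(t_n), Vectorize(function(i, j) {
    length(intersect(idx[[i]], idx[[j]]))
  }))
  mismatch <- abs(realized - ov)
  diag(mismatch) <- 0
  if (any(mismatch > 0)) {
    warn(paste0(
      "requested pairwise overlap pattern is not exactly realizable by ",
      "interval allocation; realized overlaps returned in `overlap_realized`"
    ))
  }
  list(index = idx, n_pool = max(vapply(idx, max, 1L)), realized = realized)
}

#' Simulate per-trait GWAS summary statistics under a genetic factor model
#'
#' Draws per-SNP true effects from the latent factor model in `truth`
#' (factor-mediated plus trait-specific components, infinitesimal scale
#' `1/m`), simulates individual-level cohorts on a shared genotype pool so
#' that sample overlap arises mechanistically, and computes per-SNP marginal
#' regression summary statistics for each trait.
#'
#' Genotypes are generated block by block and never held in memory as one
#' pool-sized matrix; two passes with identical block seeds first accumulate
#' polygenic values, then the marginal regressions.
#'
#' @param truth A [genetic_truth()].
#' @param panel A [snp_panel_spec()]; per-SNP effects are small relative to
#'   phenotype scale when `n_snps` is large (polygenic regime).
#' @param seed Integer seed.
#'
#' @return A list: `sumstats` (named list of per-trait tibbles with columns
#'   SNP, A1, A2, BETA, SE, P, N, FRQ; BETA on the per-allele scale),
#'   `s_true` (generating genetic covariance), `overlap_realized`,
#'   `snp_meta`, and `effects` (true per-SNP standardized trait effects and
#'   factor effects).
#' @export
simulate_multitrait_gwas <- function(truth, panel, seed) {
  if (!inherits(truth, "genetic_truth")) abort("`truth` must be a genetic_truth.")
  if (!inherits(panel, "snp_panel_spec")) abort("`panel` must be a snp_panel_spec.")
  t_n <- length(truth$trait_names)
  m <- panel$n_snps
  seeds <- derive_seeds(seed, 3L + panel$n_blocks)
  meta <- panel_snp_meta(panel, panel$meta_seed)
  blocks <- split(seq_len(m), meta$block)
  alloc <- allocate_cohorts(truth)
  n_pool <- alloc$n_pool

  # true per-SNP effects on the standardized-genotype / standardized-trait scale
  k <- ncol(truth$loadings)
  eff <- with_seed(seeds[2], {
    a <- matrix(rnorm(m * k), m, k) %*% chol(truth$factor_corr) / sqrt(m)
    e <- sapply(seq_len(t_n), function(i) {
      rnorm(m, sd = sqrt(truth$residual_h2[i] / m))
    })
    list(factor = a, beta_std = a %*% t(truth$loadings) + e)
  })

  sdx <- sqrt(2 * meta$maf * (1 - meta$maf))
  mux <- 2 * meta$maf

  # genotype blocks are cached (integer storage) when the pool fits
  # comfortably in memory; otherwise regenerated from the block seeds on
  # the second pass
  cache_ok <- as.double(n_pool) * m <= 1.6e8
  block_cache <- if (cache_ok) vector("list", length(blocks)) else NULL
  gen_block <- function(b) {
    if (cache_ok && !is.null(block_cache[[b]])) return(block_cache[[b]])
    x <- with_seed(
      seeds[3L + b],
      sample_block_dosages(n_pool, meta$maf[blocks[[b]]],
                           panel$within_block_corr)
    )
    if (cache_ok) block_cache[[b]] <<- x
    x
  }

  # pass 1: polygenic values for the pool. Standardization is folded into
  # the effect matrix so no centered copy of the dosage block is made.
  g_pool <- matrix(0, n_pool, t_n)
  for (b in seq_along(blocks)) {
    j <- blocks[[b]]
    x <- gen_block(b)
    b_scaled <- eff$beta_std[j, , drop = FALSE] / pmax(sdx[j], 1e-12)
    g_pool <- g_pool + x %*% b_scaled -
      rep(colSums(mux[j] * b_scaled), each = n_pool)
  }

  # environmental residuals: correlated across traits for shared individuals
  env_sd <- sqrt(pmax(1 - truth$total_h2, 0))
  c_env <- truth$env_corr * outer(env_sd, env_sd)
  env <- with_seed(seeds[3], {
    ce <- psd_smooth(c_env)$mat
    matrix(rnorm(n_pool * t_n), n_pool, t_n) %*% chol(ce + diag(1e-12, t_n))
  })
  y_pool <- g_pool + env

  # pass 2: per-SNP marginal regressions per cohort. With y centered,
  # x'y on raw dosages equals the centered cross-product, so only column
  # sums and sums of squares are needed per cohort (no centered copies).
  beta <- se <- matrix(NA_real_, m, t_n)
  idx_key <- vapply(alloc$index, function(i) {
    paste(range(i), collapse = ":")
  }, "")
  yc_list <- lapply(seq_len(t_n), function(i) {
    y <- y_pool[alloc$index[[i]], i]
    y - mean(y)
  })
  for (b in seq_along(blocks)) {
    j <- blocks[[b]]
    x <- gen_block(b)
    storage.mode(x) <- "double"
    sums_cache <- list()
    for (i in seq_len(t_n)) {
      idx <- alloc$index[[i]]
      n_i <- length(idx)
      key <- idx_key[i]
      if (is.null(sums_cache[[key]])) {
        xi <- x[idx, , drop = FALSE]
        sums_cache[[key]] <- list(
          xi = xi,
          s1 = colSums(xi),
          s2 = colSums(xi * xi)
        )
      }
      sc <- sums_cache[[key]]
      yc <- yc_list[[i]]
      xx <- sc$s2 - sc$s1^2 / n_i
      xx[xx == 0] <- NA_real_ # monomorphic in cohort
      xy <- crossprod(sc$xi, yc)[, 1]
      b_ji <- xy / xx
      sig2 <- pmax((sum(yc^2) - b_ji * xy) / (n_i - 2), 1e-300)
      beta[j, i] <- b_ji
      se[j, i] <- sqrt(sig2 / xx)
    }
  }

  sumstats <- lapply(seq_len(t_n), function(i) {
    z <- beta[, i] / se[, i]
    tibble::tibble(
      SNP = meta$id, A1 = meta$a1, A2 = meta$a2,
      BETA = beta[, i], SE = se[, i],
      P = 2 * pnorm(-abs(z)),
      N = length(alloc$index[[i]]), FRQ = meta$maf
    )
  })
  names(sumstats) <- truth$trait_names

  list(
    sumstats = sumstats,
    s_true = truth$s_true,
    overlap_realized = alloc$realized,
    snp_meta = dplyr::select(meta, -"block"),
    effects = list(factor = eff$factor, beta_std = eff$beta_std)
  )
}
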