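#' Compute LD scores from a reference genotype panel
#'
#' The LD score of SNP j is the sum of bias-adjusted squared correlations
#' `r2_adj = r2 - (1 - r2) / (n - 2)` with every panel SNP within
#' `window_snps` positions on either side, including itself.
#'
#' @param g A `genotype_data` reference panel (>= 2 individuals).
#' @param window_snps One-sided window width, in SNPs.
#' @return A tibble: `SNP`, `L2`, `n_ref`.
#' @export
compute_ld_scores <- function(g, window_snps = 100L) {
  if (!inherits(g, "genotype_data")) abort("`g` must be a genotype_data.")
  stop_if_not_count(window_snps, "window_snps")
  x <- g$dosage
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n < 3) abort("reference panel needs at least 3 individuals")
  m <- ncol(x)
  mu <- colMeans(x, na.rm = TRUE)
  for (j in which(colSums(is.na(x)) > 0)) x[is.na(x[, j]), j] <- mu[j]
  sdv <- apply(x, 2, sd)
  z <- sweep(sweep(x, 2, colMeans(x)), 2, pmax(sdv, 1e-12), `/`)
  l2 <- numeric(m)
  chunk <- 256L
  starts <- seq(1L, m, by = chunk)
  for (s in starts) {
    cols <- s:min(s + chunk - 1L, m)
    win <- max(1L, s - window_snps):min(m, max(cols) + window_snps)
    r <- crossprod(z[, cols, drop = FALSE], z[, win, drop = FALSE]) / (n - 1)
    r2 <- r^2
    r2a <- r2 - (1 - r2) / (n - 2)
    keep <- abs(outer(cols, win, `-`)) <= window_snps
    mono <- sdv[cols] == 0
    l2[cols] <- rowSums(r2a * keep)
    l2[cols][mono] <- 0
  }
  tibble::tibble(SNP = g$snp_meta$id, L2 = l2, n_ref = n)
}

# weighted least squares of y on [1, x]; returns intercept/slope plus
# delete-a-block jackknife SEs computed with fixed weights
wls_jackknife <- function(x, y, w, n_blocks) {
  n <- length(y)
  n_blocks <- min(n_blocks, n)
  block <- ceiling(seq_along(y) / (n / n_blocks))
  xmat <- cbind(1, x)
  wx <- xmat * w
  xtx_b <- array(0, c(2, 2, n_blocks))
  xty_b <- matrix(0, 2, n_blocks)
  for (b in seq_len(n_blocks)) {
    i <- which(block == b)
    xtx_b[, , b] <- crossprod(wx[i, , drop = FALSE], xmat[i, , drop = FALSE])
    xty_b[, b] <- crossprod(wx[i, , drop = FALSE], y[i])
  }
  xtx <- apply(xtx_b, c(1, 2), sum)
  xty <- rowSums(xty_b)
  est <- solve(xtx, xty)
  loo <- vapply(seq_len(n_blocks), function(b) {
    solve(xtx - xtx_b[, , b], xty - xty_b[, b])
  }, numeric(2))
  mean_loo <- rowMeans(loo)
  se <- sqrt((n_blocks - 1) / n_blocks *
               rowSums((loo - mean_loo)^2))
  list(est = est, se = se, loo = loo, n_blocks = n_blocks)
}

#' Univariate LD-score regression
#'
#' Regresses per-SNP association chi-square `(beta/se)^2` on
#' `N * L2 / m`, so the slope estimates the SNP heritability `h2` and the
#' free intercept captures confounding not proportional to LD. Weights are
#' `1 / L2` on a first pass and inverse-variance
#' (`1 / (L2 (1 + N h2 L2 / m)^2)`) on a second; standard errors come from
#' a delete-a-block jackknife over `n_blocks` contiguous SNP blocks.
#'
#' @param ss Sumstats tibble.
#' @param ld LD-score tibble from [compute_ld_scores()].
#' @param m Number of SNPs the heritability is spread over (defaults to the
#'   number of regression SNPs).
#' @param n_blocks Jackknife blocks.
#' @param min_snps Minimum overlapping SNPs required.
#' @param weights `"iterated"` (default) or `"inverse_ld"`.
#' @return A list: `h2`, `h2_se`, `intercept`, `intercept_se`, `n_snps`,
#'   `mean_chi2`.
#' @export
ldsc_univariate <- function(ss, ld, m = NULL, n_blocks = 200L,
                            min_snps = 200L,
                            weights = c("iterated", "inverse_ld")) {
  weights <- match.arg(weights)
  mg <- dplyr::inner_join(ss, ld, by = "SNP")
  if (nrow(mg) < min_snps) {
    abort(sprintf("only %d SNPs overlap the LD scores (need >= %d)",
                  nrow(mg), min_snps))
  }
  m <- m %||% nrow(mg)
  chi2 <- (mg$BETA / mg$SE)^2
  l2 <- pmax(mg$L2, 1) # floor used for weights only
  x <- mg$N * mg$L2 / m
  if (var(x) == 0) abort("degenerate LD-score variance")
  w <- 1 / l2
  fit <- wls_jackknife(x, chi2, w, n_blocks)
  if (weights == "iterated") {
    # floor the predicted chi-square so a poor first pass cannot give a
    # handful of SNPs explosive inverse-variance weights
    h2_0 <- max(fit$est[2], 0)
    pred <- pmax(fit$est[1] + h2_0 * x, 0.5)
    w <- 1 / (l2 * pred^2)
    w[!is.finite(w)] <- 0
    fit <- wls_jackknife(x, chi2, w, n_blocks)
  }
  list(h2 = fit$est[2], h2_se = fit$se[2],
       intercept = fit$est[1], intercept_se = fit$se[1],
       n_snps = nrow(mg), mean_chi2 = mean(chi2),
       loo = fit$loo)
}

# align z-scores of ss2 to the allele orientation of ss1 (shared SNPs only)
align_z_pair <- function(ss1, ss2) {
  common <- intersect(ss1$SNP, ss2$SNP)
  a <- ss1[match(common, ss1$SNP), ]
  b <- ss2[match(common, ss2$SNP), ]
  same <- a$A1 == b$A1 & a$A2 == b$A2
  flip <- a$A1 == b$A2 & a$A2 == b$A1
  keep <- same | flip
  a <- a[keep, ]
  b <- b[keep, ]
  z2 <- (b$BETA / b$SE) * ifelse(flip[keep], -1, 1)
  list(snp = a$SNP, z1 = a$BETA / a$SE, z2 = z2, n1 = a$N, n2 = b$N,
       n_dropped = sum(!keep))
}

#' Bivariate LD-score regression
#'
#' Regresses the per-SNP z-score product on `sqrt(N1 N2) * L2 / m`; the
#' slope estimates the genetic covariance of the two (standardized) traits
#' and the free intercept absorbs correlated estimation error from sample
#' overlap. Symmetric in its arguments; allele orientations are reconciled
#' by sign-flipping z-scores, irreconcilable SNPs are dropped.
#'
#' @inheritParams ldsc_univariate
#' @param ss1,ss2 Sumstats tibbles for the two traits.
#' @return A list: `gcov`, `gcov_se`, `intercept`, `intercept_se`,
#'   `n_snps`.
#' @export
ldsc_bivariate <- function(ss1, ss2, ld, m = NULL, n_blocks = 200L,
                           min_snps = 200L,
                           weights = c("iterated", "inverse_ld")) {
  weights <- match.arg(weights)
  pair <- align_z_pair(ss1, ss2)
  mg <- dplyr::inner_join(
    tibble::tibble(SNP = pair$snp, z1 = pair$z1, z2 = pair$z2,
                   n1 = pair$n1, n2 = pair$n2),
    ld,
    by = "SNP"
  )
  if (nrow(mg) < min_snps) {
    abort(sprintf("only %d SNPs overlap across both tables (need >= %d)",
                  nrow(mg), min_snps))
  }
  m <- m %||% nrow(mg)
  l2 <- pmax(mg$L2, 1) # floor used for weights only
  x <- sqrt(mg$n1 * mg$n2) * mg$L2 / m
  if (var(x) == 0) abort("degenerate LD-score variance")
  y <- mg$z1 * mg$z2
  w <- 1 / l2
  fit <- wls_jackknife(x, y, w, n_blocks)
  if (weights == "iterated") {
    # inverse-variance weights from the expected second moments
    u1 <- ldsc_univariate(ss1, ld, m, n_blocks, min_snps, "inverse_ld")
    u2 <- ldsc_univariate(ss2, ld, m, n_blocks, min_snps, "inverse_ld")
    e1 <- pmax(u1$intercept + pmax(u1$h2, 0) * mg$n1 * l2 / m, 0.5)
    e2 <- pmax(u2$intercept + pmax(u2$h2, 0) * mg$n2 * l2 / m, 0.5)
    ey <- fit$est[1] + fit$est[2] * x
    w <- 1 / (l2 * (e1 * e2 + ey^2))
    w[!is.finite(w) | w < 0] <- 0
    fit <- wls_jackknife(x, y, w, n_blocks)
  }
  list(gcov = fit$est[2], gcov_se = fit$se[2],
       intercept = fit$est[1], intercept_se = fit$se[1],
       n_snps = nrow(mg), n_dropped = pair$n_dropped,
       loo = fit$loo)
}

#' Assemble the genetic covariance matrix S and its sampling covariance V
#'
#' Runs univariate LD-score regression on each trait (diagonal of S) and
#' bivariate regression on each pair (off-diagonals), using one shared set
#' of contiguous genome blocks for a delete-a-block jackknife; V is the
#' jackknife covariance of the half-vectorized S across blocks, so it
#' captures dependence between S elements. S is smoothed to the nearest
#' positive semi-definite matrix by eigenvalue clipping when needed (the
#' perturbation norm is recorded).
#'
#' @param all_ss Named list of >= 2 sumstats tibbles.
#' @param ld LD-score tibble.
#' @param n_blocks Shared jackknife blocks.
#' @param m Heritability SNP count (defaults to the common-universe size).
#' @param weights Weighting scheme passed to the per-pair regressions;
#'   `"inverse_ld"` (1 / L2) avoids the small downward slope bias the
#'   data-estimated inverse-variance weights carry at desk-scale SNP
#'   counts, at a modest efficiency cost.
#' @return A `genetic_cov` object: `trait_names`, `S`, `V` (q x q over
#'   vech order, documented as column-major lower triangle), `intercepts`,
#'   `m_snps`, `smoothing`.
#' @export
build_genetic_cov <- function(all_ss, ld, n_blocks = 200L, m = NULL,
                              weights = c("iterated", "inverse_ld",
                                          "mixed")) {
  # "mixed": 1/L2 weights for the univariate regressions (slope unbiased
  # at desk-scale SNP counts, jackknife SEs conservative) and iterated
  # inverse-variance weights for the bivariate ones (they de-leverage
  # high-LD SNPs, which stabilizes the overlap intercept)
  weights <- match.arg(weights)
  w_uni <- if (weights == "mixed") "inverse_ld" else weights
  w_biv <- if (weights == "mixed") "iterated" else weights
  t_n <- length(all_ss)
  if (t_n < 2) abort("need at least 2 traits")
  names(all_ss) <- names(all_ss) %||% paste0("trait", seq_len(t_n))
  common <- Reduce(intersect, c(lapply(all_ss, `[[`, "SNP"), list(ld$SNP)))
  if (length(common) == 0) abort("empty common SNP universe")
  ldc <- ld[match(common, ld$SNP), ]
  ssc <- lapply(all_ss, function(s) s[match(common, s$SNP), ])
  m <- m %||% length(common)

  idx <- vech_index(t_n)
  q <- nrow(idx)
  est <- numeric(q)
  loo <- matrix(0, n_blocks_eff <- min(n_blocks, length(common)), q)
  intercepts <- matrix(NA_real_, t_n, t_n,
                       dimnames = list(names(all_ss), names(all_ss)))
  for (qq in seq_len(q)) {
    i <- idx[qq, 2] # col (first trait)
    j <- idx[qq, 1] # row
    res <- tryCatch(
      if (i == j) {
        u <- ldsc_univariate(ssc[[i]], ldc, m, n_blocks_eff,
                             weights = w_uni)
        intercepts[i, i] <- u$intercept
        list(est = u$h2, loo = u$loo[2, ])
      } else {
        b <- ldsc_bivariate(ssc[[i]], ssc[[j]], ldc, m, n_blocks_eff,
                            weights = w_biv)
        intercepts[i, j] <- intercepts[j, i] <- b$intercept
        list(est = b$gcov, loo = b$loo[2, ])
      },
      error = function(e) {
        abort(sprintf("LD-score regression failed for pair (%s, %s): %s",
                      names(all_ss)[i], names(all_ss)[j],
                      conditionMessage(e)))
      }
    )
    est[qq] <- res$est
    loo[, qq] <- res$loo
  }
  centered <- sweep(loo, 2, colMeans(loo))
  v <- (n_blocks_eff - 1) / n_blocks_eff * crossprod(centered)
  v_sm <- psd_smooth(v)
  s_mat <- unvech(est, t_n)
  dimnames(s_mat) <- list(names(all_ss), names(all_ss))
  s_sm <- psd_smooth(s_mat)
  structure(
    list(
      trait_names = names(all_ss),
      S = s_sm$mat, S_raw = s_mat,
      V = v_sm$mat,
      loo = loo, # per-block leave-one-out estimates of vech(S)
      intercepts = intercepts,
      m_snps = length(common),
      n_blocks = n_blocks_eff,
      smoothing = list(S_perturbation = s_sm$perturbation,
                       V_perturbation = v_sm$perturbation)
    ),
    class = "genetic_cov"
  )
}

#' @export
print.genetic_cov <- function(x, ...) {
  cat(sprintf("<genetic_cov> %d traits, %d SNPs, %d jackknife blocks\n",
              length(x$trait_names), x$m_snps, x$n_blocks))
  print(round(x$S, 4))
  invisible(x)
}

#' Serialize / restore a genetic covariance bundle
#'
#' Writes the S and V matrices, intercepts and metadata as one YAML file.
#'
#' @param gc A `genetic_cov`.
#' @param path Output path.
#' @return `path` (write) or a `genetic_cov` (read).
#' @export
write_genetic_cov <- function(gc, path) {
  yaml::write_yaml(
    list(
      trait_names = gc$trait_names,
      S = apply(gc$S, 1, as.numeric, simplify = FALSE),
      V = apply(gc$V, 1, as.numeric, simplify = FALSE),
      intercepts = apply(gc$intercepts, 1, as.numeric, simplify = FALSE),
      m_snps = gc$m_snps, n_blocks = gc$n_blocks,
      vech_order = "column-major lower triangle"
    ),
    path,
    precision = 15L
  )
  invisible(path)
}

#' @rdname write_genetic_cov
#' @export
read_genetic_cov <- function(path) {
  obj <- yaml::read_yaml(path)
  t_n <- length(obj$trait_names)
  s <- matrix(unlist(obj$S), t_n, t_n, byrow = TRUE,
              dimnames = list(obj$trait_names, obj$trait_names))
  q <- t_n * (t_n + 1) / 2
  v <- matrix(unlist(obj$V), q, q, byrow = TRUE)
  ints <- matrix(unlist(obj$intercepts), t_n, t_n, byrow = TRUE,
                 dimnames = list(obj$trait_names, obj$trait_names))
  structure(
    list(trait_names = obj$trait_names, S = s, S_raw = s, V = v,
         intercepts = ints, m_snps = obj$m_snps, n_blocks = obj$n_blocks,
         smoothing = list(S_perturbation = 0, V_perturbation = 0)),
    class = "genetic_cov"
  )
}
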