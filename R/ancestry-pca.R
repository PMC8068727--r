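# PCA on mean-imputed, variance-standardized dosages. Monomorphic SNPs are
# excluded rather than divided by zero. Returns scores (n x k) ordered by
# decreasing explained variance.
genotype_pca <- function(dosage, k) {
  x <- dosage
  mu <- colMeans(x, na.rm = TRUE)
  for (j in which(colSums(is.na(x)) > 0)) x[is.na(x[, j]), j] <- mu[j]
  sdv <- apply(x, 2, sd)
  keep <- which(sdv > 0)
  if (length(keep) == 0L) abort("all SNPs are monomorphic; PCA impossible")
  x <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], `/`)
  n <- nrow(x)
  k <- min(k, n - 1L, length(keep))
  # eigen on the smaller Gram matrix; scores = U d
  gram <- tcrossprod(x) / ncol(x)
  ev <- eigen(gram, symmetric = TRUE)
  scores <- ev$vectors[, seq_len(k), drop = FALSE] *
    rep(sqrt(pmax(ev$values[seq_len(k)], 0) * ncol(x)), each = n)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, variance = ev$values[seq_len(k)])
}

#' Two-stage ancestry PCA sample selection
#'
#' Stage 1 runs a PCA on all individuals (mean-imputed, standardized
#' dosages) and retains the individuals carrying `label` whose scores on
#' PCs 1 and 2 both lie within `mean +/- sd_window * SD`, where the mean and
#' SD are computed over the stage-1 reference population (all individuals
#' by default). Stage 2 re-runs the PCA within the retained sample and
#' attaches the top `n_pcs_out` ancestry-specific PC scores (mean-centered)
#' to the sample metadata.
#'
#' @param g A `genotype_data` object with a `group` column in `sample_meta`.
#' @param label Group label defining the target ancestry sample.
#' @param sd_window Width of the retention window in stage-1 SDs.
#' @param n_pcs_out Number of ancestry-specific PCs to attach.
#' @param reference `"all"` (default) computes the stage-1 window mean/SD on
#'   every individual; `"label"` restricts it to the labelled subsample.
#'
#' @return The retained `genotype_data`, with `PC1..PCk` columns appended to
#'   `sample_meta`.
#' @export
ancestry_pca_select <- function(g, label, sd_window = 1.0, n_pcs_out = 10L,
                                reference = c("all", "label")) {
  if (!inherits(g, "genotype_data")) abort("`g` must be a genotype_data.")
  reference <- match.arg(reference)
  stop_if_not_count(n_pcs_out, "n_pcs_out")

  stage1 <- genotype_pca(g$dosage, 2L)
  sc <- stage1$scores
  ref <- if (reference == "all") seq_len(nrow(sc)) else
    which(g$sample_meta$group == label)
  mu <- colMeans(sc[ref, , drop = FALSE])
  sdv <- apply(sc[ref, , drop = FALSE], 2, sd)
  inside <- abs(sc[, 1] - mu[1]) <= sd_window * sdv[1] &
    abs(sc[, 2] - mu[2]) <= sd_window * sdv[2]
  keep <- which(inside & g$sample_meta$group == label)

  if (length(keep) < n_pcs_out + 1L) {
    abort(sprintf(
      "only %d individuals retained; need at least n_pcs_out + 1 = %d",
      length(keep), n_pcs_out + 1L
    ))
  }
  sub <- new_genotype_data(
    g$dosage[keep, , drop = FALSE],
    g$snp_meta,
    g$sample_meta[keep, , drop = FALSE]
  )
  stage2 <- genotype_pca(sub$dosage, n_pcs_out)
  pcs <- sweep(stage2$scores, 2, colMeans(stage2$scores))
  sub$sample_meta <- dplyr::bind_cols(
    dplyr::select(sub$sample_meta, !dplyr::starts_with("PC")),
    tibble::as_tibble(pcs)
  )
  sub
}
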