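#' Regression-method factor scores
#'
#' Scores each row as `Psi Lambda' Sigma(theta)^(-1) (x - mu)` using the
#' fitted group's parameter matrices (submatrices over the observed entries
#' when a row has missing indicators), then standardizes each factor's
#' scores within sample.
#'
#' @param fit A converged `sem_fit`.
#' @param data Data frame with the indicator columns (and the grouping
#'   column for multi-group fits).
#' @param group Name of the grouping column for multi-group fits.
#' @return A tibble with one column per factor.
#' @export
factor_scores <- function(fit, data, group = NULL) {
  if (!inherits(fit, "sem_fit")) abort("`fit` must be a sem_fit")
  if (!fit$converged) abort("cannot score from a non-converged fit")
  spec <- fit$spec
  k <- length(spec$factors)
  if (k == 0) abort("the fitted model has no factors")
  data <- as.data.frame(data)
  y <- as.matrix(data[, spec$indicators, drop = FALSE])
  storage.mode(y) <- "double"
  n_groups <- length(fit$matrices)
  gi_of_row <- if (n_groups > 1) {
    if (is.null(group)) abort("multi-group fit needs `group`")
    match(as.character(data[[group]]), names(fit$stats))
  } else {
    rep(1L, nrow(y))
  }
  scores <- matrix(NA_real_, nrow(y), k)
  for (gi in seq_len(n_groups)) {
    rows <- which(gi_of_row == gi)
    if (!length(rows)) next
    mats <- fit$matrices[[gi]]
    imp <- fit$implied[[gi]]
    mu <- imp$mu
    if (!fit$mean_structure) mu <- fit$stats[[gi]]$m
    w_full <- mats$psi %*% t(mats$lambda)
    for (i in rows) {
      obs <- which(!is.na(y[i, ]))
      if (!length(obs)) next
      sig_o <- imp$sigma[obs, obs, drop = FALSE]
      inv <- tryCatch(solve(sig_o), error = function(e) NULL)
      if (is.null(inv)) abort("singular implied covariance while scoring")
      scores[i, ] <- w_full[, obs, drop = FALSE] %*% inv %*%
        (y[i, obs] - mu[obs])
    }
  }
  for (j in seq_len(k)) {
    s <- scores[, j]
    sdv <- sd(s, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) abort("degenerate factor scores")
    scores[, j] <- (s - mean(s, na.rm = TRUE)) / sdv
  }
  colnames(scores) <- spec$factors
  tibble::as_tibble(scores)
}

#' Random split-half partition
#'
#' Splits `data` into disjoint, exhaustive random halves of sizes
#' `ceiling(n/2)` (test) and `floor(n/2)` (holdout), deterministically for
#' a given seed.
#'
#' @param data Data frame (n >= 2 rows).
#' @param seed Integer seed.
#' @return A list with `test` and `holdout` tibbles.
#' @export
#' @examples
#' split_half(data.frame(x = 1:6003), seed = 1) |> lapply(nrow)
split_half <- function(data, seed) {
  n <- nrow(data)
  if (is.null(n) || n < 2) abort("need at least 2 rows to split")
  idx <- with_seed(seed, sample.int(n, ceiling(n / 2)))
  list(
    test = tibble::as_tibble(data[sort(idx), , drop = FALSE]),
    holdout = tibble::as_tibble(data[sort(setdiff(seq_len(n), idx)), ,
                                     drop = FALSE])
  )
}
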