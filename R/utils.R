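# internal helpers shared across modules

# half-vectorization index table for a p x p symmetric matrix, column-major
# over the lower triangle: (1,1), (2,1), ..., (p,1), (2,2), ...
vech_index <- function(p) {
  idx <- which(lower.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
}

vech <- function(m) m[lower.tri(m, diag = TRUE)][order_vech(nrow(m))]

# lower.tri() extracts column-major already in (col, row) order; keep identity
order_vech <- function(p) seq_len(p * (p + 1) / 2)

unvech <- function(v, p) {
  m <- matrix(0, p, p)
  m[lower.tri(m, diag = TRUE)] <- v
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

stop_if_not_count <- function(x, name) {
  if (!is_count(x)) abort(sprintf("`%s` must be a single positive integer.", name))
  invisible(as.integer(x))
}

# deterministic child seeds derived from one master seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

# nearest-PSD smoothing by eigenvalue clipping; returns matrix + perturbation
psd_smooth <- function(m, floor_frac = 1e-10) {
  dn <- dimnames(m)
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE)
  floorv <- max(abs(ev$values)) * floor_frac
  if (all(ev$values >= floorv)) {
    dimnames(m) <- dn
    return(list(mat = m, perturbation = 0, smoothed = FALSE))
  }
  vals <- pmax(ev$values, floorv)
  out <- ev$vectors %*% (vals * t(ev$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dn
  list(mat = out, perturbation = norm(out - m, "F"), smoothed = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
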