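# shared fixtures built in code

ind6 <- c("neg_affect", "anxiety", "depress",
          "impulsivity", "trait_anger", "state_anger")

spec_one <- function(ind = ind6) factor_model_spec(ind)

spec_two <- function(ind = ind6) {
  factor_model_spec(ind, list(INT = ind[1:3], EXT = ind[4:6]))
}

# exact-covariance sample: rows whose sample covariance equals `sigma`
empirical_mvn <- function(n, sigma, seed = 1) {
  p <- ncol(sigma)
  x <- withr::with_seed(seed, matrix(rnorm(n * p), n, p))
  x <- scale(x, center = TRUE, scale = FALSE)
  x <- x %*% solve(chol(cov(x)))
  x %*% chol(sigma)
}

# closed-form standardized loadings of a just-identified 3-indicator
# one-factor model on a correlation matrix
loadings_closed_form <- function(s12, s13, s23) {
  c(sqrt(s12 * s13 / s23), sqrt(s12 * s23 / s13), sqrt(s13 * s23 / s12))
}

# random PSD one-factor-compatible 3x3 correlation matrix
random_cor3 <- function() {
  l <- runif(3, 0.3, 0.95)
  s <- tcrossprod(l)
  diag(s) <- 1
  s
}

# small genotype_data built directly from a dosage matrix
toy_genotypes <- function(dosage, a1 = NULL, a2 = NULL) {
  m <- ncol(dosage)
  snp <- tibble::tibble(
    id = sprintf("rs%03d", seq_len(m)), chr = 1L,
    pos = seq_len(m) * 100L,
    a1 = a1 %||% rep("A", m), a2 = a2 %||% rep("G", m)
  )
  colnames(dosage) <- snp$id
  latentpgs:::new_genotype_data(
    dosage, snp,
    tibble::tibble(id = sprintf("i%03d", seq_len(nrow(dosage))),
                   group = "grp")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
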