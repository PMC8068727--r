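#' Specify a confirmatory factor model
#'
#' Describes a measurement model: which indicator loads on which factor,
#' whether factor covariances are free, whether a mean structure is
#' estimated, and how the factors are identified. The same specification
#' object drives both the phenotypic CFA ([fit_cfa()]) and the genetic
#' factor model ([fit_gsem()]).
#'
#' @param indicators Ordered character vector of indicator names.
#' @param loadings Named list mapping each factor name to the indicators
#'   loading on it (cross-loadings allowed).
#' @param factor_cov `"free"` (factors correlate) or `"fixed_zero"`
#'   (orthogonal factors).
#' @param mean_structure Estimate indicator intercepts? Automatically on in
#'   multi-group fits and under full-information likelihood.
#' @param identification `"unit_variance"` fixes each factor variance to 1
#'   (the default, matching a standardized presentation); `"first_loading"`
#'   fixes the first loading of each factor to 1.
#' @param fixed_residuals Optional named numeric vector fixing selected
#'   indicator residual variances (e.g. `c(MDD = 0)` after a Heywood case).
#'
#' @return An object of class `factor_model_spec`.
#' @export
#' @examples
#' factor_model_spec(
#'   indicators = c("neg_affect", "anxiety", "depress", "impulsivity",
#'                  "trait_anger", "state_anger"),
#'   loadings = list(
#'     INT = c("neg_affect", "anxiety", "depress"),
#'     EXT = c("impulsivity", "trait_anger", "state_anger")
#'   )
#' )
factor_model_spec <- function(indicators,
                              loadings = list(F1 = indicators),
                              factor_cov = c("free", "fixed_zero"),
                              mean_structure = FALSE,
                              identification = c("unit_variance",
                                                 "first_loading"),
                              fixed_residuals = NULL) {
  factor_cov <- match.arg(factor_cov)
  identification <- match.arg(identification)
  if (anyDuplicated(indicators)) abort("duplicate indicator names")
  if (is.null(names(loadings)) || any(names(loadings) == "")) {
    abort("`loadings` must be a named list (factor name -> indicators)")
  }
  unknown <- setdiff(unlist(loadings), indicators)
  if (length(unknown)) {
    abort(sprintf("loading pattern refers to unknown indicator(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  orphan <- setdiff(indicators, unlist(loadings))
  if (length(orphan)) {
    abort(sprintf("indicator(s) load on no factor: %s",
                  paste(orphan, collapse = ", ")))
  }
  if (!is.null(fixed_residuals)) {
    if (is.null(names(fixed_residuals)) ||
        !all(names(fixed_residuals) %in% indicators)) {
      abort("`fixed_residuals` must be named by indicator")
    }
  }
  structure(
    list(
      indicators = indicators, factors = names(loadings),
      pattern = loadings, factor_cov = factor_cov,
      mean_structure = mean_structure, identification = identification,
      fixed_residuals = fixed_residuals
    ),
    class = "factor_model_spec"
  )
}

#' @export
print.factor_model_spec <- function(x, ...) {
  cat(sprintf("<factor_model_spec> %d indicators, %d factor(s)\n",
              length(x$indicators), length(x$factors)))
  for (f in x$factors) {
    cat(sprintf("  %s =~ %s\n", f, paste(x$pattern[[f]], collapse = " + ")))
  }
  invisible(x)
}

# Parameter table for a (multi-group) model. One row per model parameter:
# group, mat in {lambda, psi, theta, nu, alpha}, row, col, free (shared
# positive id, 0 = fixed), value (fixed value or start).
#
# `level` encodes cross-group equality constraints:
#   configural - none; metric - loadings equal (factor variances free in
#   groups > 1); scalar - + intercepts equal (factor means free in groups
#   > 1); residual - + residual variances equal.
build_ptab <- function(spec, n_groups = 1L,
                       level = c("configural", "metric", "scalar", "residual"),
                       mean_structure = spec$mean_structure) {
  level <- match.arg(level)
  p <- length(spec$indicators)
  k <- length(spec$factors)
  rows <- list()
  next_id <- 0L
  new_id <- function() {
    next_id <<- next_id + 1L
    next_id
  }
  eq_loadings <- level %in% c("metric", "scalar", "residual") && n_groups > 1
  eq_intercepts <- level %in% c("scalar", "residual") && n_groups > 1
  eq_residuals <- level == "residual" && n_groups > 1

  lambda_ids <- matrix(0L, p, k)
  theta_ids <- rep(0L, p)
  nu_ids <- rep(0L, p)
  psi_diag_ids <- rep(0L, k)
  psi_off_ids <- matrix(0L, k, k)

  for (g in seq_len(n_groups)) {
    # loadings
    for (ki in seq_len(k)) {
      ind <- match(spec$pattern[[ki]], spec$indicators)
      for (pos in seq_along(ind)) {
        i <- ind[pos]
        fixed_first <- spec$identification == "first_loading" && pos == 1L
        if (fixed_first) {
          id <- 0L
          val <- 1
        } else if (eq_loadings && g > 1) {
          id <- lambda_ids[i, ki]
          val <- NA_real_
        } else {
          id <- new_id()
          if (g == 1) lambda_ids[i, ki] <- id
          val <- NA_real_
        }
        rows[[length(rows) + 1L]] <-
          list(group = g, mat = "lambda", row = i, col = ki,
               free = id, value = val)
      }
    }
    # factor variances
    for (ki in seq_len(k)) {
      if (spec$identification == "unit_variance") {
        # fixed 1 in the reference group; free in later groups once loadings
        # are constrained (otherwise the model would be over-restricted)
        if (g == 1 || !eq_loadings) {
          id <- 0L
          val <- 1
        } else {
          id <- new_id()
          val <- NA_real_
        }
      } else {
        id <- new_id()
        val <- NA_real_
      }
      rows[[length(rows) + 1L]] <-
        list(group = g, mat = "psi", row = ki, col = ki,
             free = id, value = val)
    }
    # factor covariances
    if (k > 1) {
      for (k2 in 2:k) {
        for (k1 in seq_len(k2 - 1)) {
          if (spec$factor_cov == "free") {
            id <- new_id()
            val <- NA_real_
          } else {
            id <- 0L
            val <- 0
          }
          rows[[length(rows) + 1L]] <-
            list(group = g, mat = "psi", row = k2, col = k1,
                 free = id, value = val)
        }
      }
    }
    # residual variances
    for (i in seq_len(p)) {
      nm <- spec$indicators[i]
      if (!is.null(spec$fixed_residuals) &&
          nm %in% names(spec$fixed_residuals)) {
        id <- 0L
        val <- unname(spec$fixed_residuals[nm])
      } else if (eq_residuals && g > 1) {
        id <- theta_ids[i]
        val <- NA_real_
      } else {
        id <- new_id()
        if (g == 1) theta_ids[i] <- id
        val <- NA_real_
      }
      rows[[length(rows) + 1L]] <-
        list(group = g, mat = "theta", row = i, col = i,
             free = id, value = val)
    }
    # intercepts and factor means
    if (mean_structure) {
      for (i in seq_len(p)) {
        if (eq_intercepts && g > 1) {
          id <- nu_ids[i]
        } else {
          id <- new_id()
          if (g == 1) nu_ids[i] <- id
        }
        rows[[length(rows) + 1L]] <-
          list(group = g, mat = "nu", row = i, col = 1L,
               free = id, value = NA_real_)
      }
      for (ki in seq_len(k)) {
        if (eq_intercepts && g > 1) {
          id <- new_id() # factor means free in non-reference groups
          val <- NA_real_
        } else {
          id <- 0L
          val <- 0
        }
        rows[[length(rows) + 1L]] <-
          list(group = g, mat = "alpha", row = ki, col = 1L,
               free = id, value = val)
      }
    }
  }
  ptab <- as.data.frame(dplyr::bind_rows(lapply(rows, tibble::as_tibble)))
  attr(ptab, "n_free") <- max(c(0L, ptab$free))
  attr(ptab, "by_group") <- lapply(seq_len(n_groups), function(g) {
    sel <- ptab$group == g
    list(mat = ptab$mat[sel], row = ptab$row[sel], col = ptab$col[sel],
         free = ptab$free[sel], value = ptab$value[sel])
  })
  ptab
}

ptab_group <- function(ptab, group) {
  bg <- attr(ptab, "by_group")
  if (!is.null(bg) && group <= length(bg)) return(bg[[group]])
  sel <- ptab$group == group
  list(mat = ptab$mat[sel], row = ptab$row[sel], col = ptab$col[sel],
       free = ptab$free[sel], value = ptab$value[sel])
}

# materialize model matrices for one group from the parameter table + theta
ptab_matrices <- function(ptab, theta, spec, group) {
  p <- length(spec$indicators)
  k <- length(spec$factors)
  sub <- ptab_group(ptab, group)
  val <- sub$value
  val[sub$free > 0] <- theta[sub$free[sub$free > 0]]
  lam <- matrix(0, p, k)
  psi <- diag(0, k)
  th <- rep(0, p)
  nu <- rep(0, p)
  alpha <- rep(0, k)
  for (r in seq_along(val)) {
    m <- sub$mat[r]
    if (m == "lambda") {
      lam[sub$row[r], sub$col[r]] <- val[r]
    } else if (m == "psi") {
      psi[sub$row[r], sub$col[r]] <- val[r]
      psi[sub$col[r], sub$row[r]] <- val[r]
    } else if (m == "theta") {
      th[sub$row[r]] <- val[r]
    } else if (m == "nu") {
      nu[sub$row[r]] <- val[r]
    } else {
      alpha[sub$row[r]] <- val[r]
    }
  }
  dimnames(lam) <- list(spec$indicators, spec$factors)
  dimnames(psi) <- list(spec$factors, spec$factors)
  list(lambda = lam, psi = psi, theta = th, nu = nu, alpha = alpha)
}
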