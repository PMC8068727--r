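#' Assemble a study configuration
#'
#' A config carries either file paths to real data or a synthetic-truth
#' block, plus model specifications, grouping variables for invariance
#' testing, decision thresholds and the master seed. Exactly one of
#' `paths` / `synthetic` must be supplied.
#'
#' @param synthetic Optional list with elements `phenotype` (list: `truth`
#'   a [pheno_truth()], `n`, optional `groups` label vector, optional
#'   `coupling` list(`factor`, `h2`) linking the phenotypic factor to a
#'   genetic factor), `genetic` (list: `truth` a [genetic_truth()],
#'   `panel` a [snp_panel_spec()]), and `target` (list: `n` genotyped
#'   target individuals).
#' @param paths Optional list: `genotypes` (PLINK prefix), `format`,
#'   `sumstats` (named vector of files), `phenotypes` (TSV with id column).
#' @param models List with phenotypic specs `pheno_one`, `pheno_two` and
#'   genetic specs `genetic_one`, `genetic_two` (each a
#'   [factor_model_spec()]; genetic ones optional).
#' @param grouping Character vector of phenotype-table columns to run
#'   invariance ladders over (e.g. gender, age band).
#' @param thresholds Decision thresholds; defaults: RMSEA <= 0.06 and
#'   CFI/TLI >= 0.90 acceptable fit, depreciation at CFI drop > 0.01 or
#'   RMSEA rise > 0.015, factor-distinctness alert at r > 0.80, power gate
#'   adjusted R2 >= 0.008.
#' @param seed Master seed; all stage seeds derive from it.
#' @param ancestry_label Group label used for ancestry PCA selection.
#' @return A `study_config`.
#' @export
study_config <- function(synthetic = NULL, paths = NULL, models,
                         grouping = character(0),
                         thresholds = list(), seed = 1L,
                         ancestry_label = NULL) {
  if (is.null(synthetic) == is.null(paths)) {
    abort("exactly one of `synthetic` or `paths` must be given")
  }
  if (!"pheno_one" %in% names(models)) {
    abort("`models` must contain at least `pheno_one`")
  }
  th <- utils::modifyList(
    list(rmsea_max = 0.06, cfi_min = 0.90, tli_min = 0.90,
         delta_cfi = 0.01, delta_rmsea = 0.015,
         corr_alert = 0.80, power_gate = 0.008),
    thresholds
  )
  structure(
    list(synthetic = synthetic, paths = paths, models = models,
         grouping = grouping, thresholds = th, seed = as.integer(seed),
         ancestry_label = ancestry_label),
    class = "study_config"
  )
}

# generate or load all study inputs; returns list(phenotypes, genotypes,
# sumstats, ld, notes)
acquire_study_data <- function(cfg) {
  seeds <- derive_seeds(cfg$seed, 6L)
  out <- list(phenotypes = NULL, genotypes = NULL, sumstats = NULL,
              gwas_truth = NULL)
  if (!is.null(cfg$paths)) {
    p <- cfg$paths
    if (!is.null(p$genotypes)) {
      out$genotypes <- read_genotypes(p$genotypes, p$format %||% "plink")
    }
    if (!is.null(p$sumstats)) {
      out$sumstats <- lapply(p$sumstats, read_sumstats)
      names(out$sumstats) <- names(p$sumstats) %||%
        paste0("trait", seq_along(p$sumstats))
    }
    if (!is.null(p$phenotypes)) {
      out$phenotypes <- tibble::as_tibble(
        read.table(p$phenotypes, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
      )
    }
    return(out)
  }
  syn <- cfg$synthetic
  if (!is.null(syn$genetic)) {
    gwas <- simulate_multitrait_gwas(syn$genetic$truth, syn$genetic$panel,
                                     seed = seeds[1])
    out$sumstats <- gwas$sumstats
    out$gwas_truth <- gwas
  }
  if (!is.null(syn$target)) {
    if (is.null(syn$genetic)) abort("`target` genotypes need a `genetic` block")
    out$genotypes <- simulate_genotypes(syn$target$n, syn$genetic$panel,
                                        seed = seeds[2])
  }
  if (!is.null(syn$phenotype)) {
    ph <- syn$phenotype
    groups <- ph$groups %||% ph$truth$group_names[1]
    if (is.null(ph$coupling) || is.null(out$genotypes)) {
      out$phenotypes <- simulate_phenotype_panel(ph$n, ph$truth, groups,
                                                 seed = seeds[3])
      if (!is.null(out$genotypes) && ph$n == nrow(out$genotypes$dosage)) {
        out$phenotypes$id <- out$genotypes$sample_meta$id
      }
    } else {
      out$phenotypes <- simulate_coupled_phenotypes(
        out$genotypes, out$gwas_truth, ph, seed = seeds[3]
      )
    }
  }
  out
}

# phenotype panel whose factor is partly the target individuals' true
# genetic factor value (polygenic signal), so PGS-phenotype associations
# have known ground truth
simulate_coupled_phenotypes <- function(g, gwas, ph, seed) {
  truth <- ph$truth
  cp <- ph$coupling
  k_all <- ncol(gwas$effects$factor)
  wts <- cp$weights %||% {
    w0 <- rep(0, k_all)
    w0[cp$factor %||% 1L] <- 1
    w0
  }
  x <- g$dosage
  storage.mode(x) <- "double"
  maf <- g$snp_meta$maf %||% (colMeans(x, na.rm = TRUE) / 2)
  xs <- sweep(sweep(x, 2, 2 * maf), 2, pmax(sqrt(2 * maf * (1 - maf)),
                                            1e-12), `/`)
  gval <- as.vector(xs %*% (gwas$effects$factor %*% wts))
  gval <- (gval - mean(gval)) / sd(gval)
  n <- nrow(x)
  p <- length(truth$indicators)
  k <- ncol(truth$loadings)
  with_seed(seed, {
    h2c <- cp$h2 %||% 0.2
    f <- sqrt(h2c) * gval + sqrt(1 - h2c) * rnorm(n)
    fmat <- matrix(f, n, k) # shared polygenic factor across pheno factors
    y <- fmat %*% t(truth$loadings) +
      matrix(rnorm(n * p), n, p) %*% diag(truth$residual_sd, p)
    if (!is.null(truth$nuisance_loadings)) {
      y <- y + tcrossprod(rnorm(n), truth$nuisance_loadings)
    }
    colnames(y) <- truth$indicators
    res <- tibble::tibble(id = g$sample_meta$id,
                          group = truth$group_names[1])
    res <- dplyr::bind_cols(res, tibble::as_tibble(y))
    attr(res, "truth_scores") <- fmat
    res
  })
}

#' Run the full study workflow
#'
#' Executes, in order: genotype QC, two-stage ancestry PCA,
#' negative-loading phenotype screening, split-half partition, one- versus
#' two-factor phenotypic models on the test half with the delta-criteria
#' verdict and the factor-distinctness alert, holdout refit of the accepted
#' structure, measurement-invariance ladders, individual polygenic scores,
#' LD-score regression and the genetic factor models, latent polygenic
#' scores, and PGS-factor association models. Stages without inputs (e.g.
#' no summary statistics) are skipped and recorded as such. Any stage
#' failure aborts with the stage named; the partial report is attached to
#' the error condition.
#'
#' @param cfg A [study_config()].
#' @return A `study_report`.
#' @export
run_study <- function(cfg) {
  if (!inherits(cfg, "study_config")) abort("`cfg` must be a study_config")
  th <- cfg$thresholds
  seeds <- derive_seeds(cfg$seed + 104729L, 4L)
  report <- list(config_seed = cfg$seed, stages = list())
  note <- function(stage, status, ...) {
    report$stages[[stage]] <<- c(list(status = status), list(...))
  }
  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e) {
      note(stage, "failed", error = conditionMessage(e))
      abort(
        sprintf("study stage `%s` failed: %s", stage, conditionMessage(e)),
        report = structure(report, class = "study_report")
      )
    })
  }

  dat <- run_stage("acquire", acquire_study_data(cfg))
  note("acquire", "done",
       has_genotypes = !is.null(dat$genotypes),
       has_sumstats = !is.null(dat$sumstats),
       has_phenotypes = !is.null(dat$phenotypes))

  # --- genetic preprocessing -------------------------------------------
  g <- NULL
  if (!is.null(dat$genotypes)) {
    qc <- run_stage("qc", qc_filter(dat$genotypes))
    report$qc <- tidy(qc$report)
    note("qc", "done")
    g <- run_stage("ancestry_pca", ancestry_pca_select(
      qc$genotypes,
      label = cfg$ancestry_label %||% qc$genotypes$sample_meta$group[1]
    ))
    note("ancestry_pca", "done", n_retained = nrow(g$dosage))
  } else {
    note("qc", "skipped", reason = "no genotype data")
    note("ancestry_pca", "skipped", reason = "no genotype data")
  }

  # --- phenotypic models -----------------------------------------------
  if (is.null(dat$phenotypes)) {
    abort("the study needs a phenotype table")
  }
  pheno <- dat$phenotypes
  scr <- run_stage("screening", screen_negative_loadings(
    pheno, cfg$models$pheno_one, estimator = "ml_robust"
  ))
  report$screening <- list(dropped = scr$dropped)
  note("screening", "done", dropped = scr$dropped)
  spec1 <- scr$spec
  spec2 <- cfg$models$pheno_two
  if (!is.null(spec2) && length(scr$dropped)) {
    pat2 <- lapply(spec2$pattern, function(i) setdiff(i, scr$dropped))
    pat2 <- pat2[vapply(pat2, length, 0L) > 0]
    spec2 <- factor_model_spec(setdiff(spec2$indicators, scr$dropped), pat2,
                               factor_cov = spec2$factor_cov)
  }

  halves <- run_stage("split_half", split_half(pheno, seed = seeds[1]))
  note("split_half", "done",
       n_test = nrow(halves$test), n_holdout = nrow(halves$holdout))

  fit1 <- run_stage("test_one_factor",
                    fit_cfa(halves$test, spec1, estimator = "ml_robust"))
  report$test_one_factor <- glance(fit1)
  note("test_one_factor", "done")
  accepted_spec <- spec1
  accepted_label <- "one_factor"
  if (!is.null(spec2)) {
    fit2 <- run_stage("test_two_factor",
                      fit_cfa(halves$test, spec2, estimator = "ml_robust"))
    report$test_two_factor <- glance(fit2)
    note("test_two_factor", "done")
    cmp <- run_stage("model_comparison", compare_models(
      free = fit2, restricted = fit1,
      delta_cfi = th$delta_cfi, delta_rmsea = th$delta_rmsea
    ))
    std2 <- standardized_solution(fit2)
    r_inter <- std2$std_estimate[std2$mat == "psi"][1] %||% NA_real_
    alert <- is.finite(r_inter) && abs(r_inter) > th$corr_alert
    # Decision rule: an inadmissible two-factor solution (factor
    # correlation outside [-1, 1] or a Heywood case) cannot support
    # distinct factors and yields the one-factor model outright.
    # Otherwise the parsimony rule applies: one-factor accepted when the
    # two-factor model offers no delta-criteria improvement, with the
    # factor-distinctness alert (|r| above the alert level) reported as
    # corroborating diagnostic. thresholds$require_alert additionally
    # demands the alert fire before parsimony is applied.
    one_ok <- !fit2$admissible ||
      (cmp$verdict == "equivalent" &&
         (!isTRUE(th$require_alert) || alert))
    if (one_ok) {
      accepted_label <- "one_factor"
      accepted_spec <- spec1
    } else {
      accepted_label <- "two_factor"
      accepted_spec <- spec2
    }
    report$model_comparison <- dplyr::mutate(
      cmp, inter_factor_corr = r_inter, corr_alert = alert,
      two_factor_admissible = fit2$admissible,
      accepted = accepted_label
    )
    note("model_comparison", "done", accepted = accepted_label)
  } else {
    note("test_two_factor", "skipped", reason = "no two-factor spec")
  }

  holdout_fit <- run_stage("holdout_refit", fit_cfa(
    halves$holdout, accepted_spec, estimator = "ml_robust"
  ))
  report$holdout_fit <- glance(holdout_fit)
  note("holdout_refit", "done")

  if (length(cfg$grouping)) {
    report$invariance <- list()
    for (gv in cfg$grouping) {
      lad <- run_stage(paste0("invariance_", gv), invariance_ladder(
        pheno, accepted_spec, grouping = gv
      ))
      report$invariance[[gv]] <- list(
        highest_level_attained = lad$highest_level_attained,
        table = tidy(lad)
      )
      note(paste0("invariance_", gv), "done",
           attained = lad$highest_level_attained)
    }
  }

  # --- polygenic scores -------------------------------------------------
  pgs_tab <- NULL
  if (!is.null(dat$sumstats) && !is.null(g)) {
    pgs_tab <- run_stage("individual_pgs", {
      purrr::imap(dat$sumstats, function(ss, tr) {
        attr(ss, "trait") <- tr
        compute_pgs(g, harmonize_weights(ss, g))
      })
    })
    report$pgs_descriptives <- dplyr::bind_rows(lapply(pgs_tab, function(p) {
      tibble::tibble(trait = p$trait[1], n = nrow(p),
                     n_snps = p$n_snps_used[1])
    }))
    note("individual_pgs", "done", n_scores = length(pgs_tab))
  } else {
    note("individual_pgs", "skipped",
         reason = "no summary statistics or genotypes")
  }

  # --- genomic SEM ------------------------------------------------------
  latent_tab <- NULL
  if (!is.null(dat$sumstats) && length(dat$sumstats) >= 2 && !is.null(g)) {
    gsem_out <- run_stage("gsem", {
      ld <- compute_ld_scores(g, window_snps = min(200L, ncol(g$dosage)))
      gcov <- build_genetic_cov(dat$sumstats, ld,
                                n_blocks = min(200L, gcov_blocks(ld)))
      gfit1 <- if (!is.null(cfg$models$genetic_one)) {
        fit_gsem(gcov, cfg$models$genetic_one)
      }
      gfit2 <- if (!is.null(cfg$models$genetic_two)) {
        fit_gsem(gcov, cfg$models$genetic_two)
      }
      list(gcov = gcov, one = gfit1, two = gfit2)
    })
    report$genetic_cov <- list(
      S = gsem_out$gcov$S, intercepts = gsem_out$gcov$intercepts,
      m_snps = gsem_out$gcov$m_snps
    )
    if (!is.null(gsem_out$one)) report$gsem_one <- glance(gsem_out$one)
    if (!is.null(gsem_out$two)) report$gsem_two <- glance(gsem_out$two)
    if (!is.null(gsem_out$one) && !is.null(gsem_out$two)) {
      report$gsem_comparison <- tryCatch(
        compare_gsem(free = gsem_out$two, restricted = gsem_out$one),
        error = function(e) NULL
      )
    }
    note("gsem", "done")
    fits_for_weights <- purrr::compact(list(one = gsem_out$one,
                                            two = gsem_out$two))
    fits_for_weights <- purrr::keep(fits_for_weights, "converged")
    if (length(fits_for_weights)) {
      latent_tab <- run_stage("latent_pgs", {
        out <- list()
        for (nm in names(fits_for_weights)) {
          lws <- latent_snp_weights(gsem_out$gcov, fits_for_weights[[nm]],
                                    dat$sumstats)
          for (fac in names(lws)) {
            wt <- as_weight_table(lws[[fac]])
            wt <- wt[wt$id %in% g$snp_meta$id, , drop = FALSE]
            out[[make.unique(c(names(out), fac))[length(out) + 1L]]] <-
              compute_pgs(g, wt)
          }
        }
        out
      })
      note("latent_pgs", "done", factors = names(latent_tab))
    }
  } else {
    note("gsem", "skipped", reason = "genetic inputs incomplete")
    note("latent_pgs", "skipped", reason = "genetic inputs incomplete")
  }

  # --- associations -----------------------------------------------------
  if (!is.null(pgs_tab) || !is.null(latent_tab)) {
    assoc <- run_stage("association", {
      scores <- factor_scores(holdout_fit, halves$holdout)
      adf <- dplyr::bind_cols(
        tibble::tibble(id = halves$holdout$id),
        scores
      )
      pcs <- dplyr::select(g$sample_meta, "id", dplyr::starts_with("PC"))
      adf <- dplyr::inner_join(adf, pcs, by = "id")
      all_pgs <- c(pgs_tab %||% list(), latent_tab %||% list())
      rows <- list()
      for (tr in names(all_pgs)) {
        p <- all_pgs[[tr]]
        col <- paste0("pgs_", tr)
        adf2 <- dplyr::inner_join(
          adf, setNames(p[, c("id", "z_score")], c("id", col)), by = "id"
        )
        pcs_here <- grep("^PC", names(adf2), value = TRUE)
        for (fac in colnames(scores)) {
          rows[[paste(tr, fac)]] <-
            regress_with_pcs(adf2, fac, col, pcs = pcs_here)
        }
      }
      dplyr::bind_rows(rows)
    })
    report$associations <- dplyr::mutate(
      assoc,
      interpretable = .data$adj_r2 >= th$power_gate
    )
    note("association", "done", n_models = nrow(assoc))
  } else {
    note("association", "skipped", reason = "no polygenic scores")
  }

  report$accepted_model <- accepted_label
  report$thresholds <- th
  structure(report, class = "study_report")
}

gcov_blocks <- function(ld) max(10L, min(200L, floor(nrow(ld) / 25L)))

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  for (st in names(x$stages)) {
    s <- x$stages[[st]]
    cat(sprintf("  %-20s %s\n", st, s$status))
  }
  cat("  accepted phenotypic model:", x$accepted_model %||% "none", "\n")
  invisible(x)
}

#' Serialize a study report to JSON
#'
#' @param report A `study_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_report <- function(report, path) {
  jsonlite::write_json(
    unclass(report), path,
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE
  )
  invisible(path)
}
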