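#' Adjust phenotypes for contemporary group and age
#'
#' Ordinary least-squares fit of the trait on contemporary-group factors, an
#' age covariate and an intercept; the residuals are the adjusted phenotypes
#' used for accuracy and bias scoring. Animals in singleton contemporary
#' groups get residual exactly 0 (their group dummy absorbs them); a warning
#' flags such groups.
#'
#' @param ph phenotype tibble with `animal_id`, `trait`, `cg`, `age`.
#' @return tibble `animal_id`, `y_adj` (NA for animals without a trait
#'   record).
#' @export
adjust_phenotypes <- function(ph) {
  need <- c("animal_id", "trait", "cg", "age")
  if (!all(need %in% names(ph))) abort("phenotype table needs animal_id, trait, cg, age")
  obs <- !is.na(ph$trait)
  dat <- ph[obs, , drop = FALSE]
  dat$cg <- droplevels(factor(dat$cg))
  singletons <- names(which(table(dat$cg) == 1))
  if (length(singletons) > 0) {
    warn(paste0("singleton contemporary group(s): ",
                paste(singletons, collapse = ", "),
                "; their residuals are forced to 0"))
  }
  fit <- stats::lm(trait ~ cg + age, data = dat)
  out <- tibble(animal_id = ph$animal_id, y_adj = NA_real_)
  out$y_adj[obs] <- unname(stats::resid(fit))
  out
}

#' Random k-fold cross-validation plan
#'
#' Uniform random partition of animals into k folds whose sizes differ by at
#' most one; deterministic given the seed. Persist the plan with
#' [write_fold_plan()] so every analysis scores the same validation groups.
#'
#' @param animal_ids character vector of animal ids.
#' @param k number of folds, default 5.
#' @param seed RNG seed.
#' @return a `fold_plan` tibble: `animal_id`, `fold`, with `k` and `seed` as
#'   attributes.
#' @export
make_folds <- function(animal_ids, k = 5, seed = 1) {
  n <- length(animal_ids)
  if (k < 2 || k > n) abort("k must be between 2 and the number of animals")
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  plan <- tibble(animal_id = as.character(animal_ids), fold = fold)
  attr(plan, "k") <- as.integer(k)
  attr(plan, "seed") <- as.integer(seed)
  class(plan) <- c("fold_plan", class(plan))
  plan
}

#' @rdname make_folds
#' @param plan a `fold_plan`.
#' @param path file path.
#' @export
write_fold_plan <- function(plan, path) {
  write_output_tsv(as_tibble(plan), path,
                   comment = paste0("k=", attr(plan, "k"), " seed=", attr(plan, "seed")))
}

#' @rdname make_folds
#' @export
read_fold_plan <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", col_types = "ci", progress = FALSE)
  plan <- tibble(animal_id = tab$animal_id, fold = tab$fold)
  attr(plan, "k") <- max(tab$fold)
  class(plan) <- c("fold_plan", class(plan))
  plan
}

#' Genomic prediction accuracy
#'
#' Pearson correlation between GEBV and the adjusted phenotype, divided by
#' the square root of the trait heritability.
#'
#' @param gebv,y_adj numeric vectors, same animals.
#' @param h2 trait heritability, default 0.20.
#' @return accuracy estimate.
#' @export
accuracy <- function(gebv, y_adj, h2 = 0.20) {
  if (h2 <= 0 || h2 > 1) abort("h2 must lie in (0, 1]")
  stats::cor(gebv, y_adj) / sqrt(h2)
}

#' Genomic prediction bias (regression slope)
#'
#' OLS slope, by default of GEBV on the adjusted phenotype (the published
#' direction); `pheno_on_gebv` gives the conventional dispersion-bias slope.
#' A slope of 1 is unbiased in either direction.
#'
#' @param gebv,y_adj numeric vectors.
#' @param direction "gebv_on_pheno" (default) or "pheno_on_gebv".
#' @return slope estimate.
#' @export
bias <- function(gebv, y_adj, direction = c("gebv_on_pheno", "pheno_on_gebv")) {
  direction <- match.arg(direction)
  if (direction == "gebv_on_pheno") {
    stats::cov(gebv, y_adj) / stats::var(y_adj)
  } else {
    stats::cov(gebv, y_adj) / stats::var(gebv)
  }
}

#' Cross-validated genomic prediction with BayesR
#'
#' For each fold, trains the sampler on the remaining animals (raw trait with
#' contemporary group and age fitted as fixed effects inside the model) and
#' predicts GEBV = X g_hat for the held-out animals; scores accuracy and both
#' bias directions against the adjusted phenotype. Origin assignment is
#' computed once from the reference panel before this function — it does not
#' use phenotypes, so there is no leakage across folds.
#'
#' @param g `phased_genotypes` of the target population.
#' @param ph phenotype tibble (all animals must have a trait here).
#' @param config a [bayesr_config()]; the sampler seed is offset by the fold
#'   number so folds are independent but reproducible.
#' @param matrix_kind "control" or "origin".
#' @param calls,ws origin calls and window set (required for
#'   `matrix_kind = "origin"`).
#' @param folds a `fold_plan`; built from `k` and `fold_seed` when NULL.
#' @param k,fold_seed fold plan parameters when `folds` is NULL.
#' @param h2 heritability used in the accuracy denominator.
#' @return a `cv_result` tibble: per fold `fold`, `n_valid`, `accuracy`,
#'   `bias`, `bias_dispersion`; overall means and standard errors of the
#'   mean (sd / sqrt(k)) as attribute `summary`.
#' @export
run_crossval <- function(g, ph, config, matrix_kind = c("control", "origin"),
                         calls = NULL, ws = NULL, folds = NULL,
                         k = 5, fold_seed = 1, h2 = 0.20) {
  matrix_kind <- match.arg(matrix_kind)
  stopifnot(inherits(g, "phased_genotypes"))
  ph <- ph[match(g$animal_ids, ph$animal_id), , drop = FALSE]
  if (anyNA(ph$animal_id) || anyNA(ph$trait)) {
    abort("every genotyped animal needs a phenotype record with a trait value")
  }
  X <- if (matrix_kind == "control") {
    build_control_xmatrix(g)
  } else {
    if (is.null(calls) || is.null(ws)) abort("origin matrix needs calls and ws")
    build_origin_xmatrix(g, calls, ws)
  }
  if (is.null(folds)) folds <- make_folds(g$animal_ids, k = k, seed = fold_seed)
  kf <- attr(folds, "k") %||% max(folds$fold)
  fold_of <- folds$fold[match(g$animal_ids, folds$animal_id)]
  if (anyNA(fold_of)) abort("fold plan does not cover all animals")
  adj <- adjust_phenotypes(ph)
  y_adj <- adj$y_adj[match(g$animal_ids, adj$animal_id)]
  ph$cg <- droplevels(factor(ph$cg))

  per_fold <- lapply(seq_len(kf), function(f) {
    train <- fold_of != f
    valid <- !train
    dat <- ph[train, , drop = FALSE]
    dat$cg <- droplevels(dat$cg)
    W <- stats::model.matrix(~ cg + age, data = dat)
    cfg_f <- config
    cfg_f$seed <- config$seed + f
    fit <- gibbs_sample(dat$trait, X[train, , drop = FALSE], fixed = W, config = cfg_f)
    gebv <- predict_gebv(X[valid, , drop = FALSE], fit$effect_mean)
    tibble(fold = f, n_valid = sum(valid),
           accuracy = accuracy(gebv, y_adj[valid], h2 = h2),
           bias = bias(gebv, y_adj[valid], "gebv_on_pheno"),
           bias_dispersion = bias(gebv, y_adj[valid], "pheno_on_gebv"))
  })
  res <- dplyr::bind_rows(per_fold)
  summ <- tibble(matrix_kind = matrix_kind, k = kf,
                 accuracy_mean = mean(res$accuracy),
                 accuracy_sem = stats::sd(res$accuracy) / sqrt(kf),
                 bias_mean = mean(res$bias),
                 bias_sem = stats::sd(res$bias) / sqrt(kf),
                 bias_dispersion_mean = mean(res$bias_dispersion))
  attr(res, "summary") <- summ
  attr(res, "matrix_kind") <- matrix_kind
  class(res) <- c("cv_result", class(res))
  res
}

#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) attr(x, "summary")

#' @export
print.cv_result <- function(x, ...) {
  s <- attr(x, "summary")
  cat("<cv_result> ", s$matrix_kind, " matrix, ", s$k, "-fold\n", sep = "")
  cat(sprintf("  accuracy %.3f (SEM %.3f), bias %.3f (SEM %.3f)\n",
              s$accuracy_mean, s$accuracy_sem, s$bias_mean, s$bias_sem))
  print(as_tibble(x))
  invisible(x)
}

#' QTL association report from a BayesR fit
#'
#' Columns (SNP x origin class) whose posterior inclusion probability meets
#' the threshold, sorted by PIP, with genomic coordinates for Manhattan-style
#' plotting.
#'
#' @param fit a `bayesr_fit`.
#' @param col_info [design_column_info()] tibble for the fitted matrix.
#' @param threshold inclusion PIP threshold, default 0.20.
#' @return tibble: `chrom`, `pos_bp`, `snp_id`, `class`, `effect`,
#'   `pip_inclusion`, sorted by decreasing PIP.
#' @export
qtl_report <- function(fit, col_info, threshold = 0.20) {
  td <- tidy(fit, col_info = col_info)
  td |>
    dplyr::filter(.data$pip_inclusion >= threshold) |>
    dplyr::arrange(dplyr::desc(.data$pip_inclusion)) |>
    dplyr::select("chrom", "pos_bp", "snp_id", "class",
                  effect = "estimate", "pip_inclusion")
}
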