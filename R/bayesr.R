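#' BayesR sampler configuration
#'
#' The mixture model puts every SNP effect in one of K normal classes with
#' variances `variance_multipliers * sigma_g2`; the first multiplier must be
#' exactly 0 (the null class) and the rest increase. Mixture proportions have
#' a Dirichlet prior.
#'
#' @param variance_multipliers ordered class variance multipliers, default
#'   c(0, 1e-4, 1e-3, 1e-2).
#' @param dirichlet_alpha Dirichlet prior concentration, default c(1,1,1,1).
#' @param n_iter total Gibbs sweeps, default 50000.
#' @param burn_in sweeps discarded, default 20000.
#' @param thin keep every `thin`-th sweep, default 10.
#' @param seed RNG seed used for the whole chain.
#' @param sigma_g_mode "sampled" (default): the genetic variance gets a
#'   scaled-inverse-chi-square update from the current nonzero effects;
#'   "fixed": held at `sigma_g_value` (or `h2_init * var(y)` if NULL).
#' @param h2_init initialisation heritability for the genetic variance,
#'   default 0.20.
#' @param sigma_g_value explicit fixed/initial genetic variance, overrides
#'   the h2-based initialisation when given.
#' @param residual_df,residual_scale scaled-inverse-chi-square prior on the
#'   residual variance; the default (-2, 0) is flat.
#' @param genetic_df,genetic_scale prior for the sampled genetic variance;
#'   `genetic_scale = NULL` sets the prior mean to `h2_init * var(y)`.
#' @param fix_pr optional simplex vector: hold the mixture proportions fixed
#'   (used for ridge/BLUP cross-checks).
#' @param fix_sigma_e optional value: hold the residual variance fixed.
#' @param centre centre design columns before sampling (densifies the
#'   matrix; default FALSE, raw dosages).
#' @param store_g_trace keep the full per-column effect trace (memory-heavy;
#'   for diagnostics on small problems).
#' @return a `bayesr_config` list.
#' @export
bayesr_config <- function(variance_multipliers = c(0, 1e-4, 1e-3, 1e-2),
                          dirichlet_alpha = c(1, 1, 1, 1),
                          n_iter = 50000L, burn_in = 20000L, thin = 10L,
                          seed = 1L,
                          sigma_g_mode = c("sampled", "fixed"),
                          h2_init = 0.20, sigma_g_value = NULL,
                          residual_df = -2, residual_scale = 0,
                          genetic_df = 4, genetic_scale = NULL,
                          fix_pr = NULL, fix_sigma_e = NULL,
                          centre = FALSE, store_g_trace = FALSE) {
  sigma_g_mode <- match.arg(sigma_g_mode)
  K <- length(variance_multipliers)
  if (K < 2) abort("need at least the null class and one nonzero class")
  if (variance_multipliers[1] != 0) abort("the first variance multiplier must be exactly 0")
  if (any(diff(variance_multipliers) <= 0)) abort("variance multipliers must increase")
  if (length(dirichlet_alpha) != K) abort("dirichlet_alpha must match the number of classes")
  if (any(dirichlet_alpha <= 0)) abort("dirichlet_alpha must be positive")
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in); thin <- as.integer(thin)
  if (burn_in >= n_iter) abort("burn_in must be smaller than n_iter")
  if (thin < 1) abort("thin must be >= 1")
  if (h2_init <= 0 || h2_init >= 1) abort("h2_init must lie in (0, 1)")
  if (!is.null(fix_pr)) {
    if (length(fix_pr) != K || any(fix_pr < 0) || abs(sum(fix_pr) - 1) > 1e-8) {
      abort("fix_pr must be a length-K simplex vector")
    }
  }
  structure(list(variance_multipliers = variance_multipliers,
                 dirichlet_alpha = dirichlet_alpha,
                 n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed),
                 sigma_g_mode = sigma_g_mode, h2_init = h2_init,
                 sigma_g_value = sigma_g_value,
                 residual_df = residual_df, residual_scale = residual_scale,
                 genetic_df = genetic_df, genetic_scale = genetic_scale,
                 fix_pr = fix_pr, fix_sigma_e = fix_sigma_e,
                 centre = centre, store_g_trace = store_g_trace),
            class = "bayesr_config")
}

as_dgc <- function(X) {
  methods::as(methods::as(methods::as(Matrix::Matrix(X, sparse = TRUE),
                                      "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

#' Fit the BayesR mixture model by Gibbs sampling
#'
#' Single-site Gibbs sampler for y = W beta + X g + e with the K-class
#' normal-mixture prior on g. Per sweep it (a) samples fixed effects from
#' their normal full conditionals under flat priors, (b) for each design
#' column samples the mixture-class indicator from its effect-integrated
#' marginal conditional and then the effect from its normal full conditional,
#' (c) samples the mixture proportions from Dirichlet(alpha + class counts),
#' (d) samples the residual variance and (e), unless fixed, the genetic
#' variance from their scaled-inverse-chi-square full conditionals. Posterior
#' summaries average the post-burn-in thinned samples.
#'
#' @param y numeric trait vector (complete; typically raw phenotypes with
#'   fixed effects supplied via `fixed`).
#' @param X design matrix, animals x columns (dense or sparse; origin or
#'   control layout).
#' @param fixed fixed-effect design: NULL for an intercept only, a numeric
#'   matrix, or a one-sided formula evaluated in `data` (an intercept is
#'   added via model.matrix). Use `fixed = "none"` for no fixed effects.
#' @param data data frame for a formula `fixed`.
#' @param config a [bayesr_config()].
#' @param col_groups optional grouping of design columns (factor/integer
#'   vector of length ncol(X), NA = ungrouped), typically the haplotype
#'   window of each column. The fit then also reports a group-level
#'   posterior inclusion probability: the share of retained draws in which
#'   ANY column of the group has a nonzero effect. This is the quantity to
#'   use for window-level QTL calls — tightly linked proxy columns split
#'   the per-column PIP among themselves, while the group statistic does
#'   not dilute.
#' @param group_share_threshold a group counts as associated in a draw when
#'   its members explain more than this share of the genetic variance
#'   explained in that draw; NULL (default) uses the proportional share
#'   1 / n_groups.
#' @return a `bayesr_fit` object: per-column posterior effect means and
#'   class-membership PIPs, inclusion PIPs, fixed-effect and variance
#'   traces, mean class counts, and the training-animal posterior-mean GEBV.
#' @export
gibbs_sample <- function(y, X, fixed = NULL, data = NULL, config = bayesr_config(),
                         col_groups = NULL, group_share_threshold = NULL) {
  stopifnot(inherits(config, "bayesr_config"))
  y <- as.numeric(y)
  if (anyNA(y) || any(!is.finite(y))) abort("y must be finite and complete")
  n <- length(y)
  if (nrow(X) != n) abort("nrow(X) must equal length(y)")
  if (is.null(fixed)) {
    W <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else if (identical(fixed, "none")) {
    W <- matrix(0, n, 0)
  } else if (inherits(fixed, "formula")) {
    W <- stats::model.matrix(fixed, data = data)
    if (nrow(W) != n) abort("fixed-effect design rows must match y (no missing covariates)")
  } else {
    W <- as.matrix(fixed)
  }
  if (ncol(W) > 0 && qr(W)$rank < ncol(W)) {
    abort("fixed-effect design is rank deficient")
  }
  col_labels <- colnames(X)
  if (config$centre) {
    X <- as.matrix(X)
    X <- sweep(X, 2, colMeans(X))
  }
  Xs <- as_dgc(X)
  vary <- stats::var(y)
  sigma_g_init <- config$sigma_g_value %||% (config$h2_init * vary)
  sample_sigma_g <- config$sigma_g_mode == "sampled"
  genetic_scale <- config$genetic_scale %||%
    (config$h2_init * vary * (config$genetic_df - 2) / config$genetic_df)
  sample_pr <- is.null(config$fix_pr)
  K <- length(config$variance_multipliers)
  pr_init <- config$fix_pr %||% (config$dirichlet_alpha / sum(config$dirichlet_alpha))
  sample_sigma_e <- is.null(config$fix_sigma_e)
  sigma_e_init <- config$fix_sigma_e %||% (0.5 * vary)
  if (!is.null(col_groups)) {
    if (length(col_groups) != ncol(Xs)) abort("col_groups must have one entry per design column")
    gf <- factor(col_groups)
    groups_int <- as.integer(gf)
    groups_int[is.na(groups_int)] <- 0L
    n_groups <- nlevels(gf)
    group_levels <- levels(gf)
  } else {
    groups_int <- integer(ncol(Xs)); n_groups <- 0L; group_levels <- character(0)
  }
  share_thr <- group_share_threshold %||% (if (n_groups > 0) 1 / n_groups else 0)

  set.seed(config$seed)
  res <- bayesr_gibbs_cpp(y, W, Xs@p, Xs@i, Xs@x, ncol(Xs),
                          config$variance_multipliers, config$dirichlet_alpha,
                          config$n_iter, config$burn_in, config$thin,
                          config$residual_df, config$residual_scale,
                          sigma_e_init,
                          sigma_g_init, sample_sigma_g,
                          config$genetic_df, genetic_scale,
                          sample_pr, pr_init,
                          sample_sigma_e,
                          config$store_g_trace,
                          groups_int, n_groups, share_thr)

  pip <- res$pip
  colnames(pip) <- paste0("pip_", seq_len(K))
  traces <- tibble(iter = res$trace_iter,
                   sigma_e2 = res$trace_sigma_e2,
                   sigma_g2 = res$trace_sigma_g2)
  pr_tr <- res$trace_pr
  colnames(pr_tr) <- paste0("pr_", seq_len(K))
  traces <- dplyr::bind_cols(traces, as_tibble(pr_tr))
  if (ncol(W) > 0) {
    beta_tr <- res$trace_beta
    colnames(beta_tr) <- colnames(W) %||% paste0("beta_", seq_len(ncol(W)))
    traces <- dplyr::bind_cols(traces, as_tibble(beta_tr))
  }
  fit <- structure(list(
    effect_mean = as.numeric(res$effect_mean),
    pip = pip,
    pip_inclusion = pip_inclusion(pip),
    beta_mean = stats::setNames(as.numeric(res$beta_mean), colnames(W)),
    class_counts_mean = as.numeric(res$class_counts_mean),
    gebv_train = as.numeric(res$gebv_mean),
    group_pip = if (n_groups > 0) stats::setNames(as.numeric(res$group_pip), group_levels) else NULL,
    incl_first_half = as.numeric(res$incl_first_half),
    incl_second_half = as.numeric(res$incl_second_half),
    n_retained = res$n_retained,
    traces = traces,
    g_trace = if (config$store_g_trace) res$trace_g else NULL,
    col_labels = col_labels,
    n = n, p = ncol(Xs),
    config = config), class = "bayesr_fit")
  fit
}

#' @export
print.bayesr_fit <- function(x, ...) {
  cat("<bayesr_fit> n =", x$n, ", columns =", x$p,
      ", retained samples =", x$n_retained, "\n")
  cat("  mean class counts:", paste(signif(x$class_counts_mean, 4), collapse = ", "), "\n")
  cat("  posterior mean sigma_e2 =", signif(mean(x$traces$sigma_e2), 4),
      " sigma_g2 =", signif(mean(x$traces$sigma_g2), 4), "\n")
  invisible(x)
}

#' Posterior inclusion probability of a nonzero effect
#'
#' PIP_inclusion = PIP_2 + ... + PIP_K, the posterior probability the column
#' falls in any nonzero variance class (equivalently 1 - PIP_1).
#'
#' @param pips matrix (columns x K) or vector (length K) of class PIPs.
#' @return numeric vector of inclusion probabilities.
#' @export
pip_inclusion <- function(pips) {
  if (is.null(dim(pips))) pips <- matrix(pips, nrow = 1)
  if (any(abs(rowSums(pips) - 1) > 1e-9)) abort("class PIPs must sum to 1")
  unname(rowSums(pips[, -1, drop = FALSE]))
}

#' Genomic estimated breeding values
#'
#' GEBV = X g_hat: the design matrix times the posterior mean SNP effects.
#' For an origin matrix, each SNP's three class columns contribute through
#' their own effects.
#'
#' @param X design matrix for the animals to predict.
#' @param g_hat posterior mean effects, or a `bayesr_fit` (its column labels
#'   are then checked against `colnames(X)`).
#' @return named numeric vector of GEBV per animal.
#' @export
predict_gebv <- function(X, g_hat) {
  if (inherits(g_hat, "bayesr_fit")) {
    fit <- g_hat
    if (!is.null(fit$col_labels) && !is.null(colnames(X)) &&
        !identical(colnames(X), fit$col_labels)) {
      abort("design columns do not match the fitted effect labels")
    }
    g_hat <- fit$effect_mean
  }
  if (ncol(X) != length(g_hat)) abort("ncol(X) must match length(g_hat)")
  out <- as.numeric(X %*% g_hat)
  names(out) <- rownames(X)
  out
}

#' @export
predict.bayesr_fit <- function(object, newdata, ...) {
  predict_gebv(newdata, object)
}

#' MCMC summary diagnostics for a BayesR fit
#'
#' Trace means of the variance components and mixture proportions, plus a
#' split-half agreement check: the correlation between inclusion PIPs
#' computed from the first and second halves of the retained samples.
#'
#' @param fit a `bayesr_fit`.
#' @return one-row tibble of diagnostics.
#' @export
mcmc_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "bayesr_fit"))
  i1 <- fit$incl_first_half; i2 <- fit$incl_second_half
  split_cor <- if (stats::sd(i1) > 0 && stats::sd(i2) > 0) stats::cor(i1, i2) else NA_real_
  tibble(n_retained = fit$n_retained,
         sigma_e2_mean = mean(fit$traces$sigma_e2),
         sigma_g2_mean = mean(fit$traces$sigma_g2),
         split_half_pip_cor = split_cor,
         mean_nonzero_columns = sum(fit$class_counts_mean[-1]))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-column posterior summary of a BayesR fit
#'
#' @param x a `bayesr_fit`.
#' @param col_info optional [design_column_info()] tibble to attach snp_id,
#'   class and position.
#' @param ... unused.
#' @return tibble: one row per design column with the posterior effect mean,
#'   the K class PIPs and the inclusion PIP.
#' @method tidy bayesr_fit
#' @export
tidy.bayesr_fit <- function(x, col_info = NULL, ...) {
  out <- tibble(col = seq_len(x$p),
                term = x$col_labels %||% paste0("col_", seq_len(x$p)),
                estimate = x$effect_mean)
  out <- dplyr::bind_cols(out, as_tibble(x$pip))
  out$pip_inclusion <- x$pip_inclusion
  if (!is.null(col_info)) {
    out <- dplyr::left_join(out, col_info, by = "col")
  }
  out
}

#' One-row fit summary
#'
#' @param x a `bayesr_fit`.
#' @param ... unused.
#' @return tibble with sizes, retained draws, posterior mean variance
#'   components and the implied variance ratio.
#' @method glance bayesr_fit
#' @export
glance.bayesr_fit <- function(x, ...) {
  se <- mean(x$traces$sigma_e2); sg <- mean(x$traces$sigma_g2)
  tibble(n = x$n, p = x$p, n_iter = x$config$n_iter, burn_in = x$config$burn_in,
         n_retained = x$n_retained, sigma_e2 = se, sigma_g2 = sg,
         var_ratio = sg / (sg + se))
}
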