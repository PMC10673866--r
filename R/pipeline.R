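#' Run the full subspecies-of-origin analysis pipeline
#'
#' Thin orchestration over the package's stages: read (or simulate) inputs,
#' build windows and reference haplotype frequencies, assign subspecies of
#' origin, build the requested design matrix, fit BayesR, and optionally
#' cross-validate and write a QTL report. Every intermediate is persisted as
#' plain TSV/MatrixMarket text, and a JSON run manifest records the config
#' hash, input checksums, seeds, stage timings, the fallback-assignment
#' fraction and every output file with its producing stage, so a rerun with
#' the same config and seed reproduces the outputs exactly.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{inputs}{either `simulate: <sim_config overrides>` or file paths
#'       `reference_vcf`, `target_vcf`, `labels`, `phenotypes`.}
#'     \item{window_kb}{haplotype window length (default 100).}
#'     \item{matrix}{"origin" (default) or "control".}
#'     \item{fallback_mode}{"as_printed" (default) or "similarity".}
#'     \item{bayesr}{overrides for [bayesr_config()].}
#'     \item{crossval}{optional: `k`, `h2`, `fold_seed` to run
#'       cross-validation.}
#'     \item{qtl_threshold}{inclusion-PIP threshold for the QTL report
#'       (default 0.20).}
#'     \item{seed}{master seed.}
#'   }
#' @param out_dir output directory (created if absent).
#' @return the run manifest, invisibly; all outputs are files in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  window_kb <- config$window_kb %||% 100
  matrix_kind <- config$matrix %||% "origin"
  fallback_mode <- config$fallback_mode %||% "as_printed"
  t0 <- Sys.time()
  timings <- list()
  outputs <- list()
  tick <- function(stage, start) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), start, units = "secs"))
  }
  register <- function(stage, path) {
    outputs[[length(outputs) + 1]] <<- list(stage = stage, file = basename(path))
    path
  }

  # ---- inputs ----
  s <- Sys.time()
  input_checksums <- list()
  if (!is.null(config$inputs$simulate) || is.null(config$inputs)) {
    sc_args <- config$inputs$simulate %||% list()
    sc_args$seed <- sc_args$seed %||% seed
    sc_args$window_kb <- sc_args$window_kb %||% window_kb
    if (!is.null(sc_args$breed_profiles)) {
      sc_args$breed_profiles <- as_tibble(sc_args$breed_profiles)
    }
    cfg <- do.call(sim_config, sc_args)
    sim <- simulate_hybrid_study(cfg)
    g_ref <- sim$ref; labels <- sim$labels; g_tgt <- sim$target
    ph <- sim$phenotypes
    write_phased_vcf(g_ref, register("inputs", file.path(out_dir, "reference.vcf")))
    write_phased_vcf(g_tgt, register("inputs", file.path(out_dir, "target.vcf")))
    write_output_tsv(labels, register("inputs", file.path(out_dir, "labels.tsv")))
    write_output_tsv(ph, register("inputs", file.path(out_dir, "phenotypes.tsv")))
    write_output_tsv(sim$truth, register("inputs", file.path(out_dir, "truth_windows.tsv")))
    write_output_tsv(sim$qtl, register("inputs", file.path(out_dir, "truth_qtl.tsv")))
  } else {
    for (f in c("reference_vcf", "target_vcf", "labels", "phenotypes")) {
      pth <- config$inputs[[f]]
      if (is.null(pth) || !file.exists(pth)) {
        abort(paste0("missing input file for '", f, "'"))
      }
      input_checksums[[f]] <- unname(tools::md5sum(pth))
    }
    g_ref <- read_phased_vcf(config$inputs$reference_vcf)
    g_tgt <- read_phased_vcf(config$inputs$target_vcf)
    labels <- read_reference_labels(config$inputs$labels)
    ph <- read_phenotypes(config$inputs$phenotypes,
                          rms_range_check = config$rms_range_check %||% TRUE)
    check_same_markers(g_ref, g_tgt)
  }
  tick("inputs", s)

  # ---- windows & reference frequencies ----
  s <- Sys.time()
  ws <- build_windows(g_ref$map, window_kb)
  ref_codes <- encode_haplotypes(g_ref, ws)
  freqs <- reference_frequencies(ref_codes, labels)
  write_frequency_tsv(freqs, register("freqs", file.path(out_dir, "haplotype_frequencies.tsv")))
  tick("freqs", s)

  # ---- origin assignment ----
  s <- Sys.time()
  tgt_codes <- encode_haplotypes(g_tgt, ws)
  calls <- assign_origins(tgt_codes, freqs, mode = fallback_mode, quiet = TRUE)
  write_origin_calls_tsv(calls, register("assign", file.path(out_dir, "origin_calls.tsv")))
  pct <- indicus_percentage(calls, breeds = ph[c("animal_id", "breed")])
  write_output_tsv(pct, register("assign", file.path(out_dir, "indicus_percentage.tsv")))
  write_output_tsv(breed_content_summary(pct),
                   register("assign", file.path(out_dir, "breed_content.tsv")))
  tick("assign", s)

  # ---- design matrix ----
  s <- Sys.time()
  if (matrix_kind == "origin") {
    X <- build_origin_xmatrix(g_tgt, calls, ws)
    col_info <- design_column_info(g_tgt$map, "origin")
  } else {
    X <- build_control_xmatrix(g_tgt)
    col_info <- design_column_info(g_tgt$map, "control")
  }
  write_design_matrix(X, register("xmatrix", file.path(out_dir, "xmatrix.mtx")),
                      col_info = col_info)
  tick("xmatrix", s)

  # ---- BayesR ----
  s <- Sys.time()
  br_args <- config$bayesr %||% list()
  br_args$seed <- br_args$seed %||% seed
  bcfg <- do.call(bayesr_config, br_args)
  ph_m <- ph[match(g_tgt$animal_ids, ph$animal_id), , drop = FALSE]
  ph_m$cg <- droplevels(factor(ph_m$cg))
  fit <- gibbs_sample(ph_m$trait, X, fixed = ~ cg + age, data = ph_m, config = bcfg)
  eff <- tidy(fit, col_info = col_info)
  write_output_tsv(eff[c("snp_id", "class", "chrom", "pos_bp", "estimate",
                         grep("^pip_", names(eff), value = TRUE))],
                   register("bayesr", file.path(out_dir, "effects.tsv")))
  gebv <- predict_gebv(X, fit$effect_mean)
  write_output_tsv(tibble(animal_id = g_tgt$animal_ids, gebv = gebv),
                   register("bayesr", file.path(out_dir, "gebv.tsv")))
  tick("bayesr", s)

  # ---- QTL report ----
  s <- Sys.time()
  rep_tbl <- qtl_report(fit, col_info, threshold = config$qtl_threshold %||% 0.20)
  write_output_tsv(rep_tbl, register("qtlmap", file.path(out_dir, "qtl_report.tsv")))
  tick("qtlmap", s)

  # ---- cross-validation (optional) ----
  if (!is.null(config$crossval)) {
    s <- Sys.time()
    cv_k <- config$crossval$k %||% 5
    cv_h2 <- config$crossval$h2 %||% 0.20
    folds <- make_folds(g_tgt$animal_ids, k = cv_k,
                        seed = config$crossval$fold_seed %||% seed)
    write_fold_plan(folds, register("crossval", file.path(out_dir, "fold_plan.tsv")))
    cv <- run_crossval(g_tgt, ph, bcfg, matrix_kind = matrix_kind,
                       calls = calls, ws = ws, folds = folds, h2 = cv_h2)
    write_output_tsv(as_tibble(cv), register("crossval", file.path(out_dir, "cv_folds.tsv")))
    write_output_tsv(glance(cv), register("crossval", file.path(out_dir, "cv_summary.tsv")))
    tick("crossval", s)
  }

  manifest <- list(
    package = as.character(utils::packageVersion("boaqtl")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config_hash = hash_config(config),
    input_checksums = input_checksums,
    window_kb = window_kb,
    matrix = matrix_kind,
    fallback_fraction = attr(calls, "fallback_fraction"),
    stage_seconds = timings,
    outputs = outputs,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# md5 of the canonical YAML serialisation of the config
hash_config <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(config), tf)
  unname(tools::md5sum(tf))
}
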