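## End-to-end orchestration: simulate (or load) -> normalize -> kernels ->
## HDMA -> permutation -> heritability -> translation, driven by one
## declarative config with a single master seed; every artifact gets a
## manifest and the run manifest records all stage checksums.

#' Read and validate a pipeline run configuration
#'
#' The config is a YAML (or already-parsed list) with top-level fields:
#' `seed` (mandatory), `outdir`, and optional blocks `simulation`
#' (arguments to [sim_config()]), `paths` (inputs for [load_dataset()];
#' exactly one of `simulation`/`paths` must be present), `hdma` (`rank`,
#' `tol`, `max_iter`), `permutation` (`n_perm`; 0 skips the stage),
#' `heritability` (`window_bp`, `max_transcripts`; `max_transcripts = 0`
#' skips), and `translate` (`enabled`; simulation runs only).
#'
#' @param config path to a YAML file, or a list.
#' @return the validated config list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config must declare a seed")
  config$seed <- as.integer(config$seed)
  if (is.null(config$outdir)) stop("config must declare an outdir")
  has_sim <- !is.null(config$simulation)
  has_paths <- !is.null(config$paths)
  if (has_sim == has_paths) {
    stop("config must declare exactly one of 'simulation' or 'paths'")
  }
  config$hdma <- modifyList(list(rank = NULL, tol = 1e-8, max_iter = 500L),
                            config$hdma %||% list())
  config$permutation <- modifyList(list(n_perm = 99L),
                                   config$permutation %||% list())
  config$heritability <- modifyList(list(window_bp = 10e6,
                                         max_transcripts = 50L),
                                    config$heritability %||% list())
  config$translate <- modifyList(list(enabled = has_sim),
                                 config$translate %||% list())
  config
}

#' Run the full mediation pipeline
#'
#' Executes every configured stage, writing each artifact with a JSON
#' manifest sidecar under `outdir`, and returns (and writes) a run-level
#' manifest with settings and per-file checksums. Rerunning with an
#' identical config reproduces identical checksums.
#'
#' @param config a YAML path or list, see [read_run_config()].
#' @return the run manifest (list), invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) {
    message(sprintf("[kermed %s] ", format(Sys.time(), "%H:%M:%S")),
            sprintf(...))
  }
  artifacts <- character(0)
  keep <- function(path) { artifacts <<- c(artifacts, path); path }

  ## stage: data
  if (!is.null(cfg$simulation)) {
    log_msg("stage simulate")
    sim_args <- cfg$simulation
    sim_args$seed <- sim_args$seed %||% cfg$seed
    scfg <- do.call(sim_config, sim_args)
    dat <- simulate_dataset(scfg)
    truth <- dat$truth
    keep(write_haplotype_dosages(dat$dosages,
                                 file.path(outdir, "dosages.tsv")))
    keep(write_omics_matrix(dat$expression,
                            file.path(outdir, "expression.tsv")))
    keep(write_omics_matrix(dat$phenotypes,
                            file.path(outdir, "phenotypes.tsv")))
    jsonlite::write_json(
      list(core_ids = truth$core_ids, core_weights = truth$core_weights,
           trait_coefs = truth$trait_coefs,
           h2_local_target = truth$h2_local_target,
           h2_distal_target = truth$h2_distal_target),
      keep(file.path(outdir, "truth.json")), auto_unbox = TRUE, digits = NA)
    expression <- dat$expression; phenotypes <- dat$phenotypes
    dosages <- dat$dosages; covariates <- NULL
  } else {
    log_msg("stage load")
    p <- cfg$paths
    dat <- load_dataset(p$dosages, unlist(p$expression), p$phenotypes,
                        p$covariates)
    expression <- if (length(dat$expression) > 1L) {
      concat_tissues(dat$expression)
    } else dat$expression[[1L]]
    phenotypes <- dat$phenotypes
    dosages <- dat$dosages
    covariates <- dat$covariates
    truth <- NULL
  }

  ## stage: normalize
  log_msg("stage normalize (%d transcripts, %d traits)",
          ncol(expression$values), ncol(phenotypes$values))
  expr_n <- normalize_features(expression)
  pheno_n <- normalize_features(phenotypes)
  if (!is.null(covariates)) {
    expr_n <- adjust_covariates(expr_n, covariates)
    pheno_n <- adjust_covariates(pheno_n, covariates)
  }

  ## stage: kernels
  log_msg("stage kernels")
  K_G <- genome_kernel(dosages)
  K_T <- linear_kernel(expr_n, modality = "transcriptome")
  K_P <- linear_kernel(pheno_n, modality = "phenome")
  keep(write_kernel(K_G, file.path(outdir, "kernel_genome.tsv")))
  keep(write_kernel(K_T, file.path(outdir, "kernel_transcriptome.tsv")))
  keep(write_kernel(K_P, file.path(outdir, "kernel_phenome.tsv")))

  ## stage: hdma
  log_msg("stage hdma")
  fit <- fit_hdma(K_G, K_T, K_P, rank = cfg$hdma$rank, tol = cfg$hdma$tol,
                  max_iter = cfg$hdma$max_iter, seed = cfg$seed,
                  anchor_traits = pheno_n)
  write_hdma_fit(fit, file.path(outdir, "scores.tsv"),
                 file.path(outdir, "fit.json"))
  keep(file.path(outdir, "scores.tsv")); keep(file.path(outdir, "fit.json"))
  loadings_t <- variable_loadings(expr_n, fit$scores[, "T_C"])
  loadings_p <- variable_loadings(pheno_n, fit$scores[, "P_C"])
  keep(write_loadings(loadings_t, file.path(outdir,
                                            "loadings_transcripts.tsv")))
  keep(write_loadings(loadings_p, file.path(outdir, "loadings_traits.tsv")))

  ## stage: permutation
  if (cfg$permutation$n_perm >= 99L) {
    log_msg("stage permute (%d permutations)", cfg$permutation$n_perm)
    perm <- permutation_null_path(K_G, K_T, K_P,
                                  n_perm = cfg$permutation$n_perm,
                                  seed = derive_seed(cfg$seed, 101L),
                                  rank = cfg$hdma$rank, tol = cfg$hdma$tol,
                                  max_iter = cfg$hdma$max_iter)
    write_permutation_result(perm, file.path(outdir, "permutation.json"),
                             file.path(outdir, "permutation_nulls.tsv"))
    keep(file.path(outdir, "permutation.json"))
    keep(file.path(outdir, "permutation_nulls.tsv"))
  } else {
    log_msg("stage permute skipped (n_perm < 99)")
    perm <- NULL
  }

  ## stage: heritability
  n_h2 <- cfg$heritability$max_transcripts
  if (is.null(n_h2) || n_h2 > 0L) {
    ann <- expr_n$feature_annotations
    if (!is.null(ann) && all(c("chrom", "tss_bp") %in% names(ann))) {
      idx <- seq_len(ncol(expr_n$values))
      if (!is.null(n_h2) && n_h2 < length(idx)) {
        # deterministic subset: highest-|loading| transcripts
        idx <- order(-abs(loadings_t$loading))[seq_len(n_h2)]
      }
      log_msg("stage heritability (%d transcripts)", length(idx))
      sub <- expr_n
      sub$values <- sub$values[, idx, drop = FALSE]
      sub$feature_annotations <- ann[idx, , drop = FALSE]
      h2 <- scan_heritability(sub, dosages,
                              window_bp = cfg$heritability$window_bp)
      rel <- trait_relevance(sub, pheno_n)
      h2$trait_relevance <- as.numeric(rel)
      keep(write_heritability(h2, file.path(outdir, "heritability.tsv")))
    } else {
      log_msg("stage heritability skipped (no positional annotations)")
      h2 <- NULL
    }
  } else h2 <- NULL

  ## stage: translate (simulated runs: independent validation population)
  report <- NULL
  if (isTRUE(cfg$translate$enabled) && !is.null(truth)) {
    log_msg("stage translate")
    vcfg_args <- cfg$simulation
    vcfg_args$seed <- derive_seed(cfg$seed, 202L)
    vcfg_args$n_individuals <- cfg$translate$n_individuals %||%
      max(100L, round((cfg$simulation$n_individuals %||% 300L) / 2))
    vcfg <- do.call(sim_config, vcfg_args)
    val <- simulate_validation_population(
      truth, vcfg, score_center = attr(phenotypes, "score_center"),
      score_scale = attr(phenotypes, "score_scale"))
    pred <- predict_scores(val$expression, loadings_t,
                           gene_map = data.frame(
                             from = loadings_t$feature_id,
                             to = sub("^[^:]*:", "", loadings_t$feature_id)))
    obs <- val$phenotypes$values[, 1L]
    report <- evaluate_prediction(pred, obs)
    write_prediction_report(report, pred, obs,
                            file.path(outdir, "translation.json"),
                            file.path(outdir, "translation.tsv"))
    keep(file.path(outdir, "translation.json"))
    keep(file.path(outdir, "translation.tsv"))
  }

  ## run manifest
  manifest <- list(
    settings = cfg[setdiff(names(cfg), "outdir")],
    package_version = as.character(utils::packageVersion("kermed")),
    path_coefficient = fit$path_coefficient,
    partials = as.list(fit$partials),
    permutation_p = if (!is.null(perm)) perm$p_value else NULL,
    translation_r = if (!is.null(report) && report$type == "continuous") {
      report$r
    } else NULL,
    files = lapply(setNames(artifacts, basename(artifacts)), function(f) {
      unname(tools::md5sum(f))
    }))
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_msg("done: %d artifacts in %s", length(artifacts), outdir)
  invisible(manifest)
}
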