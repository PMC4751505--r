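#' Pipeline run configuration
#'
#' One configuration object drives the whole analysis pipeline
#' (generate, fit, validate, analyze). Every stochastic stage derives its
#' seeds from the single master seed, so a rerun with the same
#' configuration reproduces every artifact byte for byte.
#'
#' @param outdir Output directory (created if absent).
#' @param dataset Path to a dataset TSV; defaults to the file
#'   `pipeline_generate()` writes under `outdir`.
#' @param seed Master seed.
#' @param sigma,replicates_data Noise level and replicate count for
#'   synthetic data generation.
#' @param grid [hyper_grid()] for calibration.
#' @param replicates_fit Replicate fits in [mga_fit()].
#' @param polish Polish the final fit.
#' @param cv_scheme `"loco"` (leave one condition out) or `"lobo"`
#'   (leave one data box out).
#' @param replicates_cv Replicate fits per cross-validation fold.
#' @param cv_config [ga_config()] used per CV training run.
#' @param perturbation Sensitivity perturbation fraction.
#' @return A `prostimm_run_config` list with a stable content hash.
#' @export
run_config <- function(outdir = "prostimm-run", dataset = NULL, seed = 1L,
                       sigma = 0.15, replicates_data = 5,
                       grid = hyper_grid(), replicates_fit = 20,
                       polish = TRUE, cv_scheme = c("loco", "lobo"),
                       replicates_cv = 20, cv_config = ga_config(),
                       perturbation = 0.05) {
  cv_scheme <- match.arg(cv_scheme)
  cfg <- list(outdir = outdir,
              dataset = dataset %||% file.path(outdir, "dataset.tsv"),
              seed = as.integer(seed), sigma = sigma,
              replicates_data = replicates_data, grid = grid,
              replicates_fit = replicates_fit, polish = polish,
              cv_scheme = cv_scheme, replicates_cv = replicates_cv,
              cv_config = cv_config, perturbation = perturbation)
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "outdir")])
  structure(cfg, class = "prostimm_run_config")
}

stage_seed <- function(cfg, stage) {
  # stable per-stage ladder from the master seed: hash the stage name
  # into an integer offset
  h <- rlang::hash(list(cfg$seed, stage))
  (cfg$seed + strtoi(substr(h, 1, 6), base = 16L)) %% 2147483646L + 1L
}

provenance <- function(cfg) {
  list(config_hash = cfg$hash, seed = cfg$seed,
       package_version = as.character(utils::packageVersion("prostimm")))
}

write_stage_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    abort(paste0("Missing prerequisite file `", path, "`; run ",
                 produced_by, " first."))
  }
  invisible(path)
}

ensure_outdir <- function(cfg) {
  if (!dir.exists(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE)
    message("Created output directory ", cfg$outdir)
  }
  invisible(cfg$outdir)
}

#' Pipeline stages
#'
#' Thin wrappers that chain the package's modules into a reproducible
#' file-based pipeline. `pipeline_generate()` writes a synthetic dataset
#' TSV plus a provenance sidecar; `pipeline_fit()` calibrates the model
#' and writes `fit.json`; `pipeline_validate()` writes the fold report
#' TSV for the chosen cross-validation scheme; `pipeline_analyze()`
#' writes the regimen outcome, ranking, CI-matrix, component-summary and
#' sensitivity tables. `pipeline_all()` runs the four stages in order.
#' Stages that need an upstream artifact fail with an error naming the
#' expected file. Every JSON artifact embeds the configuration hash.
#'
#' @param cfg A [run_config()].
#' @return Each stage invisibly returns the path(s) it wrote.
#' @export
pipeline_generate <- function(cfg) {
  ensure_outdir(cfg)
  ds <- generate_dataset(default_truth(),
                         noise_model(sigma = cfg$sigma,
                                     replicates = cfg$replicates_data),
                         seed = stage_seed(cfg, "generate"))
  write_dataset(ds, cfg$dataset)
  write_stage_json(c(provenance(cfg), attr(ds, "provenance")),
                   file.path(cfg$outdir, "generate.json"))
  invisible(cfg$dataset)
}

#' @rdname pipeline_generate
#' @export
pipeline_fit <- function(cfg) {
  ensure_outdir(cfg)
  require_artifact(cfg$dataset, "pipeline_generate()")
  ds <- read_dataset(cfg$dataset)
  fit <- mga_fit(ds, cfg$grid, replicates = cfg$replicates_fit,
                 seed = stage_seed(cfg, "fit"), polish = cfg$polish)
  path <- file.path(cfg$outdir, "fit.json")
  write_stage_json(c(provenance(cfg), list(
    objective = fit$objective,
    config = unclass(fit$config),
    polished = fit$polished,
    replicate_objectives = fit$replicate_objectives,
    trace = fit$trace,
    estimates = setNames(as.list(tidy(fit)$estimate), tidy(fit)$name)
  )), path)
  invisible(path)
}

#' @rdname pipeline_generate
#' @export
pipeline_validate <- function(cfg) {
  ensure_outdir(cfg)
  require_artifact(cfg$dataset, "pipeline_generate()")
  ds <- read_dataset(cfg$dataset)
  folds <- if (cfg$cv_scheme == "loco") {
    leave_one_condition_out(ds, cfg$cv_config, replicates = cfg$replicates_cv,
                            seed = stage_seed(cfg, "validate"))
  } else {
    leave_one_box_out(ds, cfg$cv_config, replicates = cfg$replicates_cv,
                      seed = stage_seed(cfg, "validate"))
  }
  path <- file.path(cfg$outdir, paste0("cv_", cfg$cv_scheme, ".tsv"))
  readr::write_tsv(folds, path)
  write_stage_json(c(provenance(cfg),
                     list(scheme = cfg$cv_scheme, n_folds = dplyr::n_distinct(folds$fold))),
                   file.path(cfg$outdir, "validate.json"))
  invisible(path)
}

#' @rdname pipeline_generate
#' @export
pipeline_analyze <- function(cfg) {
  ensure_outdir(cfg)
  fit_path <- file.path(cfg$outdir, "fit.json")
  require_artifact(fit_path, "pipeline_fit()")
  fit_json <- jsonlite::read_json(fit_path)
  params <- set_estimated(parameter_table(),
                          unlist(fit_json$estimates)[estimated_param_names])
  outcomes <- predict_all_regimens(params)
  readr::write_tsv(outcomes, file.path(cfg$outdir, "regimen_outcomes.tsv"))
  for (tp in c("I", "II")) {
    readr::write_tsv(rank_regimens(outcomes, tp),
                     file.path(cfg$outdir, paste0("ranking_type_", tp, ".tsv")))
    cim <- ci_matrix(outcomes, tp)
    readr::write_tsv(tidy(cim),
                     file.path(cfg$outdir, paste0("ci_pairs_type_", tp, ".tsv")))
    readr::write_tsv(component_summary(outcomes, cim),
                     file.path(cfg$outdir, paste0("component_summary_type_", tp, ".tsv")))
  }
  sens <- local_sensitivity(params, cfg$perturbation)
  readr::write_tsv(sens, file.path(cfg$outdir, "sensitivity.tsv"))
  write_stage_json(c(provenance(cfg), list(
    pearson_type_I_vs_II = pearson_r(outcomes$inhibition_I,
                                     outcomes$inhibition_II)$r)),
    file.path(cfg$outdir, "analyze.json"))
  invisible(file.path(cfg$outdir, "regimen_outcomes.tsv"))
}

#' @rdname pipeline_generate
#' @export
pipeline_all <- function(cfg) {
  pipeline_generate(cfg)
  pipeline_fit(cfg)
  pipeline_validate(cfg)
  pipeline_analyze(cfg)
  invisible(cfg$outdir)
}
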