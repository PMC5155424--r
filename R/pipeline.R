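# Pipeline orchestration: compose the stages (simulate -> classify ->
# ingest-ddg -> calibrate -> predict -> synergy) behind one entry point
# with config, logging and a run manifest.

#' Pipeline run configuration
#'
#' All paths are optional; stages whose inputs are absent are skipped (or,
#' for classification without a structure, degraded with a warning). Every
#' source of randomness flows from the one top-level `seed`, from which
#' per-stage sub-seeds are derived deterministically.
#'
#' @param output_dir Directory for stage outputs and the manifest.
#' @param variants_path Variant/activity table (TSV) for classification.
#' @param structure_path PDB file for the structural context.
#' @param chain Chain identifier passed to [load_structure()].
#' @param motifs_path Motif config file for [read_motif_config()].
#' @param ddg_path ddG table for [read_ddg_table()].
#' @param ddg_dialect Dialect of `ddg_path`.
#' @param pairs_path Calibration pairs table (TSV with `ddg`,
#'   `activity_pct`); when absent and `simulate` is a [synthetic_spec()],
#'   pairs are simulated.
#' @param doubles_path Double-variant table (TSV with `ddg_1`, `ddg_2`,
#'   optional `ddg_double`).
#' @param simulate Optional [synthetic_spec()] driving the simulate stage.
#' @param template Template label for ingested ddG tables.
#' @param seed Top-level integer seed.
#' @param analysis An [analysis_config()].
#' @param geometry A [geometry_config()].
#' @param n_perm Permutations for calibration significance.
#' @return A list of class `run_config`.
#' @export
run_config <- function(output_dir,
                       variants_path = NULL, structure_path = NULL,
                       chain = NULL, motifs_path = NULL,
                       ddg_path = NULL, ddg_dialect = "generic_tsv",
                       pairs_path = NULL, doubles_path = NULL,
                       simulate = NULL, template = "bovine_3QZ1_model",
                       seed = 1L, analysis = analysis_config(),
                       geometry = geometry_config(), n_perm = 10000L) {
  structure(list(output_dir = output_dir, variants_path = variants_path,
                 structure_path = structure_path, chain = chain,
                 motifs_path = motifs_path, ddg_path = ddg_path,
                 ddg_dialect = ddg_dialect, pairs_path = pairs_path,
                 doubles_path = doubles_path, simulate = simulate,
                 template = template, seed = as.integer(seed),
                 analysis = analysis, geometry = geometry,
                 n_perm = as.integer(n_perm)),
            class = "run_config")
}

stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

write_stage_tsv <- function(df, dir, name) {
  # list-columns (replica sets) are serialized as comma-joined values
  df <- dplyr::mutate(df, dplyr::across(where(is.list),
                                        ~vapply(.x, paste, character(1),
                                                collapse = ",")))
  path <- file.path(dir, name)
  readr::write_tsv(df, path, progress = FALSE)
  path
}

#' Run the pipeline end to end
#'
#' Executes every stage whose inputs the config provides, writes one TSV
#' per stage plus a JSON manifest (resolved thresholds, seed, input file
#' digests, completed stages, package version) into the output directory,
#' and returns the manifest. Outputs are deterministic given config and
#' seed. Per-stage failures are reported with the stage name; outputs of
#' completed stages are preserved.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  completed <- character(0)
  failures <- list()
  outputs <- character(0)
  run_stage <- function(stage, fn) {
    res <- tryCatch({
      out <- fn()
      completed <<- c(completed, stage)
      out
    }, error = function(e) {
      failures[[stage]] <<- conditionMessage(e)
      stage_log(stage, paste("FAILED:", conditionMessage(e)))
      NULL
    })
    res
  }

  pairs <- NULL
  if (!is.null(config$simulate)) {
    pairs <- run_stage("simulate", function() {
      spec <- config$simulate
      spec$seed <- derive_seed(config$seed, "simulate")
      p <- generate_calibration_pairs(spec)
      outputs <<- c(outputs, write_stage_tsv(p, config$output_dir,
                                             "simulated_pairs.tsv"))
      stage_log("simulate", sprintf("generated %d calibration pairs", nrow(p)))
      p
    })
  }
  if (!is.null(config$pairs_path)) {
    pairs <- run_stage("load_pairs", function() {
      readr::read_tsv(config$pairs_path, show_col_types = FALSE, progress = FALSE)
    })
  }

  ctx <- NULL
  if (!is.null(config$structure_path)) {
    ctx <- run_stage("load_structure", function() {
      load_structure(config$structure_path, chain = config$chain)
    })
  }

  if (!is.null(config$variants_path)) {
    run_stage("classify", function() {
      variants <- read_variant_table(config$variants_path)
      motifs <- if (!is.null(config$motifs_path))
        read_motif_config(config$motifs_path) else motif_annotation()
      cls <- classify_table(variants, ctx, motifs, config$geometry)
      outputs <<- c(outputs, write_stage_tsv(cls, config$output_dir,
                                             "classified_variants.tsv"))
      stage_log("classify", sprintf("classified %d variants", nrow(cls)))
      cls
    })
  }

  estimates <- NULL
  if (!is.null(config$ddg_path)) {
    estimates <- run_stage("ingest_ddg", function() {
      est <- read_ddg_table(config$ddg_path, dialect = config$ddg_dialect,
                            template = config$template)
      outputs <<- c(outputs, write_stage_tsv(est, config$output_dir,
                                             "ddg_estimates.tsv"))
      stage_log("ingest_ddg", sprintf("aggregated %d estimates", nrow(est)))
      est
    })
  }

  model <- NULL
  if (!is.null(pairs)) {
    model <- run_stage("calibrate", function() {
      m <- fit_calibration(pairs, config$analysis, n_perm = config$n_perm,
                           seed = derive_seed(config$seed, "calibrate"))
      model_df <- dplyr::bind_cols(
        tibble(intercept = m$intercept_a, slope = m$slope_b), glance(m))
      outputs <<- c(outputs, write_stage_tsv(model_df, config$output_dir,
                                             "calibration_model.tsv"))
      stage_log("calibrate", sprintf("a = %.4f, b = %.4f on %d pairs",
                                     m$intercept_a, m$slope_b, m$n_pairs))
      m
    })
  }

  if (!is.null(model) && !is.null(estimates)) {
    run_stage("predict", function() {
      pred <- predict_activity(model, estimates$ddg_mean) |>
        call_pathogenicity(config$analysis)
      pred <- dplyr::bind_cols(estimates[, "raw_label"], pred)
      outputs <<- c(outputs, write_stage_tsv(pred, config$output_dir,
                                             "predictions.tsv"))
      report <- dplyr::bind_cols(estimates, pred[, c("activity_pred_pct",
                                                     "capped",
                                                     "pathogenicity_call",
                                                     "severity_band")])
      outputs <<- c(outputs, write_report_table(
        report, file.path(config$output_dir, "report.tsv")))
      stage_log("predict", sprintf("predicted %d activities", nrow(pred)))
      pred
    })
  }

  if (!is.null(config$doubles_path)) {
    run_stage("synergy", function() {
      doubles <- readr::read_tsv(config$doubles_path, show_col_types = FALSE,
                                 progress = FALSE)
      syn <- classify_double(doubles, config$analysis)
      outputs <<- c(outputs, write_stage_tsv(syn, config$output_dir,
                                             "synergy.tsv"))
      stage_log("synergy", sprintf("classified %d double variants", nrow(syn)))
      syn
    })
  }

  inputs <- purrr::compact(list(variants = config$variants_path,
                                structure = config$structure_path,
                                motifs = config$motifs_path,
                                ddg = config$ddg_path,
                                pairs = config$pairs_path,
                                doubles = config$doubles_path))
  digests <- lapply(inputs, function(p) unname(tools::md5sum(p)))
  manifest <- list(
    package = "cyp21act",
    version = as.character(utils::packageVersion("cyp21act")),
    seed = config$seed,
    thresholds = unclass(config$analysis),
    geometry = unclass(config$geometry),
    template = config$template,
    inputs = digests,
    stages_completed = completed,
    stage_failures = failures,
    outputs = basename(outputs)
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
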