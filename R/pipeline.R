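# End-to-end orchestration: load a dataset directory (EDF + annotations),
# run feature extraction, clustering, ensemble training and LOO evaluation,
# and leave reusable artifacts plus a manifest on disk.

#' Load a dataset directory of EDF recordings and annotations
#'
#' Expects `annotations.csv` (see [read_annotations()]) and one
#' `<recording_id>.edf` per row. Each recording is read into the canonical
#' montage and, when its annotation places the seizure end inside the file,
#' cut to the postictal window.
#'
#' @param data_dir Directory containing the files.
#' @param duration Postictal window length in seconds (default 300).
#' @return Dataset list of `list(recording, annotation)` elements.
#' @export
load_dataset <- function(data_dir, duration = 300) {
  ann_path <- file.path(data_dir, "annotations.csv")
  anns <- read_annotations(ann_path)
  lapply(seq_len(nrow(anns)), function(i) {
    ann <- anns[i, , drop = FALSE]
    path <- file.path(data_dir, paste0(ann$recording_id, ".edf"))
    rec <- read_recording(path)
    rec$id <- ann$recording_id
    if (ann$seizure_end > 0 || is.na(rec$t0)) {
      rec <- extract_postictal(rec, ann, duration = duration)
    }
    list(recording = rec, annotation = ann)
  })
}

#' Write a simulated dataset to disk as EDF + CSV + ground-truth JSON
#'
#' @param dataset Output of [simulate_dataset()].
#' @param out_dir Directory to create/fill.
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  anns <- do.call(rbind, lapply(dataset, function(d) d$annotation))
  write_annotations(anns, file.path(out_dir, "annotations.csv"))
  for (d in dataset) {
    write_recording(d$recording,
                    file.path(out_dir, paste0(d$recording$id, ".edf")))
  }
  truth <- lapply(dataset, function(d) {
    list(recording_id = d$recording$id,
         archetype = if (is.null(d$archetype)) "none" else d$archetype,
         has_pges = d$annotation$has_pges,
         pges_end = d$annotation$pges_end)
  })
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

run_stage <- function(stage, code) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(code, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.1f s", stage,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full PGES detection pipeline on a dataset directory
#'
#' Stages: load -> feature extraction (cached in `out_dir/features.rds` and
#' reused on rerun with an identical configuration) -> K-means artifact
#' clustering -> sample-weighted forest ensemble on all recordings ->
#' leave-one-out evaluation. Artifacts written to `out_dir`:
#' `cluster_model.json`, `ensemble/` (one forest per cluster plus
#' `manifest.json`), `report.json`, `report.csv`, and `manifest.json`
#' recording the configuration and seed.
#'
#' @param data_dir Dataset directory (see [load_dataset()]).
#' @param out_dir Output directory for artifacts.
#' @param config A [pipeline_config()].
#' @return The `pges_eval_report` from the LOO evaluation, invisibly.
#' @export
run_pipeline <- function(data_dir, out_dir, config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dataset <- run_stage("load", load_dataset(data_dir,
                                            duration = config$map_T))
  n <- length(dataset)
  if (config$K > n) {
    stop("pipeline stage 'cluster' failed: K = ", config$K,
         " exceeds the number of recordings (", n, ")", call. = FALSE)
  }

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  cache <- file.path(out_dir, "features.rds")
  features <- NULL
  if (file.exists(cache)) {
    prev <- readRDS(cache)
    if (identical(prev$config_json, as.character(cfg_json))) {
      features <- prev$features
      message("[features] reused cache")
    }
  }
  if (is.null(features)) {
    features <- run_stage("features", precompute_features(dataset, config))
    saveRDS(list(config_json = as.character(cfg_json),
                 features = features), cache)
  }

  cl <- run_stage("cluster",
                  fit_kmeans(features$maps, K = config$K,
                             seed = config$seed))
  write_cluster_model(cl, file.path(out_dir, "cluster_model.json"))

  all_fm <- do.call(rbind, features$fms)
  ens <- run_stage("train", train_ensemble(
    all_fm, cl, params = rf_params(num_trees = config$num_trees,
                                   seed = config$seed),
    boost = config$boost))
  ens_dir <- file.path(out_dir, "ensemble")
  dir.create(ens_dir, showWarnings = FALSE)
  occupied <- which(!vapply(ens$models, is.null, logical(1L)))
  for (k in occupied) {
    saveRDS(ens$models[[k]], file.path(ens_dir, sprintf("forest_%03d.rds", k)))
  }
  jsonlite::write_json(list(clusters = occupied, boost = ens$boost,
                            num_trees = ens$params$num_trees,
                            seed = ens$params$seed,
                            n_features = length(ens$feature_names)),
                       file.path(ens_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  report <- run_stage("evaluate",
                      loo_cv(dataset, config, features = features))
  write_eval_report(report, json_path = file.path(out_dir, "report.json"),
                    csv_path = file.path(out_dir, "report.csv"))
  jsonlite::write_json(list(package = "pgesdetect",
                            version = as.character(
                              utils::packageVersion("pgesdetect")),
                            n_recordings = n,
                            config = unclass(config)),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
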