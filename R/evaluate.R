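# Recording-based evaluation: per-recording predicted time distance and the
# tolerance-based detection accuracies, plus the leave-one-out
# cross-validation driver for the full pipeline.

#' Predicted time distance for one recording
#'
#' `TD_r = |P_end - T_end|`: the absolute difference in seconds between the
#' predicted and the annotated PGES end (equivalently first-ISW) times.
#'
#' @param p_end Predicted end time in seconds (>= 0).
#' @param t_end Annotated end time in seconds (>= 0).
#' @return Non-negative number of seconds.
#' @export
time_distance <- function(p_end, t_end) {
  stopifnot(all(p_end >= 0), all(t_end >= 0))
  abs(p_end - t_end)
}

#' Aggregate time distances into the recording-based report
#'
#' `TD_avg` is the mean per-recording time distance; `Acc_5s` and `Acc_10s`
#' are the fractions of recordings whose time distance is within 5 and 10
#' seconds (tolerances inclusive).
#'
#' @param distances Non-empty numeric vector of per-recording `TD_r`
#'   (seconds), optionally named by recording id.
#' @return A `pges_eval_report`: list with `per_recording`, `TD_avg`,
#'   `TD_median`, `Acc_5s`, `Acc_10s`, `n`.
#' @export
summarize_distances <- function(distances) {
  if (length(distances) == 0L) stop("no time distances to summarize")
  stopifnot(is.numeric(distances), all(is.finite(distances)))
  structure(list(per_recording = distances,
                 TD_avg = mean(distances),
                 TD_median = median(distances),
                 Acc_5s = mean(distances <= 5),
                 Acc_10s = mean(distances <= 10),
                 n = length(distances)),
            class = "pges_eval_report")
}

#' @export
print.pges_eval_report <- function(x, ...) {
  cat(sprintf(paste0("<pges_eval_report: n = %d, TD_avg = %.2f s, ",
                     "TD_median = %.2f s, Acc_5s = %.3f, Acc_10s = %.3f>\n"),
              x$n, x$TD_avg, x$TD_median, x$Acc_5s, x$Acc_10s))
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects every tunable of the detection pipeline with its default:
#' analysis bands, epoch length, number of artifact clusters `K`, the
#' focal-cluster weight `boost`, random-forest size, the correction rule
#' (`min_run`, `conf_thresh`), the artifact-map span, and the master seed.
#'
#' @param emd_band Band for EMD-based features, Hz (default 0.5-30).
#' @param base_band Band for the baseline features, Hz (default 0.5-5).
#' @param epoch_length Epoch length in seconds (default 1).
#' @param K Number of artifact clusters (default 7).
#' @param boost Focal-cluster sample-weight multiplier (default 2).
#' @param num_trees Trees per forest (default 100).
#' @param min_run,conf_thresh Correction-rule parameters (default 3, 0.8).
#' @param map_T Artifact-map span in seconds (default 300).
#' @param max_modes EMD mode cap (default 10).
#' @param seed Master integer seed (default 1).
#' @return List of class `pges_config`.
#' @export
pipeline_config <- function(emd_band = c(0.5, 30), base_band = c(0.5, 5),
                            epoch_length = 1, K = 7L, boost = 2,
                            num_trees = 100L, min_run = 3L,
                            conf_thresh = 0.8, map_T = 300,
                            max_modes = 10L, seed = 1L) {
  stopifnot(epoch_length > 0, K >= 1L, boost >= 1, num_trees >= 1L,
            min_run >= 1L, conf_thresh >= 0, conf_thresh <= 1, map_T > 0)
  structure(list(emd_band = emd_band, base_band = base_band,
                 epoch_length = epoch_length, K = as.integer(K),
                 boost = boost, num_trees = as.integer(num_trees),
                 min_run = as.integer(min_run), conf_thresh = conf_thresh,
                 map_T = map_T, max_modes = as.integer(max_modes),
                 seed = as.integer(seed)),
            class = "pges_config")
}

#' Precompute per-recording features and artifact maps
#'
#' Feature extraction is fold-independent, so the LOO driver computes it
#' once: per recording, the labelled epoch feature matrix
#' ([build_feature_matrix()]) and the artifact feature map
#' ([artifact_feature_map()] on the 0.5-30 Hz filtered signal).
#'
#' @param dataset List of elements each holding `recording` and
#'   `annotation` (as produced by [simulate_dataset()]).
#' @param config A [pipeline_config()].
#' @return List with `fms` (named list of feature matrices) and `maps`
#'   (named list of artifact maps).
#' @export
precompute_features <- function(dataset, config = pipeline_config()) {
  ids <- vapply(dataset, function(d) d$recording$id, "")
  fms <- lapply(dataset, function(d) {
    build_feature_matrix(d$recording, d$annotation,
                         emd_band = config$emd_band,
                         base_band = config$base_band,
                         max_modes = config$max_modes)
  })
  maps <- lapply(dataset, function(d) {
    artifact_feature_map(bandpass(d$recording, config$emd_band[1L],
                                  config$emd_band[2L]),
                         T_seconds = config$map_T,
                         max_modes = config$max_modes)
  })
  list(fms = setNames(fms, ids), maps = setNames(maps, ids))
}

# ground-truth end time under the no-PGES convention (T_end = 0)
true_end_time <- function(ann) {
  if (isTRUE(ann$has_pges)) ann$pges_end else 0
}

#' Leave-one-out cross-validation of the full pipeline
#'
#' For each recording in turn: fit the K-means artifact-cluster model and
#' the sample-weighted forest ensemble on all other recordings, route the
#' held-out recording to its cluster, predict its epochs, apply the
#' confidence-based correction, read off the predicted PGES end, and score
#' the time distance against the annotation. Recordings without PGES are
#' scored against `T_end = 0`; a held-out prediction of "no suppression" is
#' scored with `P_end = 0` and flagged. Deterministic given `config$seed`.
#'
#' @param dataset List of elements each holding `recording` and
#'   `annotation`.
#' @param config A [pipeline_config()].
#' @param features Optional precomputed [precompute_features()] output
#'   (computed here when `NULL`).
#' @param predict_fun Function `(fm, map, cluster_model, ensemble)` used to
#'   produce epoch predictions for the held-out recording; defaults to
#'   [predict_recording()]. Exposed so alternative classifiers can be
#'   evaluated under the identical protocol.
#' @param progress Print one line per fold (default `FALSE`).
#' @return A `pges_eval_report` with an extra `details` data frame
#'   (id, t_end, p_end, td, status, cluster).
#' @export
loo_cv <- function(dataset, config = pipeline_config(), features = NULL,
                   predict_fun = predict_recording, progress = FALSE) {
  n <- length(dataset)
  if (n < 2L) stop("leave-one-out needs at least 2 recordings")
  if (is.null(features)) features <- precompute_features(dataset, config)
  ids <- names(features$fms)
  all_fm <- do.call(rbind, features$fms)
  rownames(all_fm) <- NULL
  params <- rf_params(num_trees = config$num_trees, seed = config$seed)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    test_id <- ids[i]
    train_ids <- ids[-i]
    cl <- fit_kmeans(features$maps[train_ids],
                     K = min(config$K, length(train_ids)),
                     seed = config$seed)
    ens <- train_ensemble(all_fm[all_fm$recording_id %in% train_ids, ],
                          cl, params = params, boost = config$boost)
    preds <- predict_fun(features$fms[[test_id]],
                         features$maps[[test_id]], cl, ens)
    preds <- correct_predictions(preds, min_run = config$min_run,
                                 conf_thresh = config$conf_thresh)
    det <- detect_pges_end(preds, epoch_length = config$epoch_length)
    p_end <- if (is.na(det$p_end)) 0 else det$p_end
    t_end <- true_end_time(dataset[[i]]$annotation)
    rows[[i]] <- data.frame(id = test_id, t_end = t_end, p_end = p_end,
                            td = time_distance(p_end, t_end),
                            status = det$status,
                            cluster = if (is.null(attr(preds, "cluster")))
                              NA_integer_ else attr(preds, "cluster"),
                            stringsAsFactors = FALSE)
    if (progress) {
      message(sprintf("fold %d/%d %s: T_end = %.1f, P_end = %.1f (%s)",
                      i, n, test_id, t_end, p_end, det$status))
    }
  }
  details <- do.call(rbind, rows)
  report <- summarize_distances(setNames(details$td, details$id))
  report$details <- details
  report
}

#' Write an evaluation report to JSON and CSV
#'
#' @param report A `pges_eval_report` from [loo_cv()] or
#'   [summarize_distances()].
#' @param json_path,csv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the list written to JSON.
#' @export
write_eval_report <- function(report, json_path = NULL, csv_path = NULL) {
  out <- list(n = report$n, TD_avg = report$TD_avg,
              TD_median = report$TD_median, Acc_5s = report$Acc_5s,
              Acc_10s = report$Acc_10s,
              per_recording = as.list(report$per_recording))
  if (!is.null(json_path)) {
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path) && !is.null(report$details)) {
    write.csv(report$details, csv_path, row.names = FALSE)
  }
  invisible(out)
}
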