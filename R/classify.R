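# Cluster-oriented sample-weighted random forests: one probability forest
# per artifact cluster, each trained with elevated case weights on the
# epochs of its own cluster's recordings; prediction routes a recording to
# its cluster's forest, then confidence-based correction smooths
# implausible short label runs before the PGES end is read off.

#' Random forest hyperparameters
#' @param num_trees Number of trees (default 100).
#' @param mtry Features per split; `NULL` = sqrt of feature count.
#' @param min_node_size Minimum node size (default 1, fully grown trees).
#' @param seed Integer seed for forest construction.
#' @return List of class `rf_params`.
#' @export
rf_params <- function(num_trees = 100L, mtry = NULL, min_node_size = 1L,
                      seed = 1L) {
  structure(list(num_trees = as.integer(num_trees), mtry = mtry,
                 min_node_size = as.integer(min_node_size),
                 seed = as.integer(seed)),
            class = "rf_params")
}

#' Per-epoch sample weights for one focal cluster
#'
#' Weight `boost` for epochs whose recording belongs to the focal cluster,
#' weight 1 for everything else — the training strategy that makes each
#' forest pay more attention to its own artifact group.
#'
#' @param fm An `epoch_feature_matrix` (possibly several recordings).
#' @param assignments Named integer vector, recording id -> cluster index.
#' @param focal_cluster Cluster index the forest focuses on.
#' @param boost Weight multiplier (>= 1) for focal-cluster epochs.
#' @return Numeric weight per row of `fm`.
#' @export
make_sample_weights <- function(fm, assignments, focal_cluster, boost) {
  stopifnot(boost >= 1)
  unknown <- setdiff(unique(fm$recording_id), names(assignments))
  if (length(unknown) > 0L) {
    stop("no cluster assignment for recording(s): ",
         paste(unknown, collapse = ", "))
  }
  cl <- assignments[fm$recording_id]
  ifelse(cl == focal_cluster, boost, 1)
}

# fit one probability forest; weights omitted entirely when all equal 1 so
# that boost = 1 reduces exactly to a plain forest with the same seed
fit_forest <- function(x, y, params, weights = NULL) {
  args <- list(x = x, y = factor(y, levels = c("suppression",
                                               "non_suppression")),
               num.trees = params$num_trees,
               min.node.size = params$min_node_size,
               probability = TRUE, seed = params$seed, num.threads = 1L,
               verbose = FALSE)
  if (!is.null(params$mtry)) args$mtry <- params$mtry
  if (!is.null(weights) && any(weights != 1)) args$case.weights <- weights
  do.call(ranger::ranger, args)
}

#' Train the cluster-oriented sample-weighted forest ensemble
#'
#' Fits one probability random forest per non-empty cluster. Forest `i` is
#' trained on all epochs, with sample weight `boost` on epochs from
#' recordings assigned to cluster `i` and weight 1 elsewhere. With `K = 1`
#' and `boost = 1` this reduces to a single plain random forest.
#'
#' @param fm Labelled `epoch_feature_matrix` over the training recordings.
#' @param cluster_model `pges_cluster_model` whose assignments cover every
#'   recording in `fm`.
#' @param params [rf_params()].
#' @param boost Focal-cluster weight multiplier (default 2).
#' @return An `swrf_ensemble`: list with `models` (cluster index ->
#'   ranger forest), `boost`, `params`, `feature_names`.
#' @export
train_ensemble <- function(fm, cluster_model, params = rf_params(),
                           boost = 2) {
  classes <- unique(fm$label)
  missing_class <- setdiff(c("suppression", "non_suppression"), classes)
  if (length(missing_class) > 0L) {
    stop("training labels contain no '", missing_class[1L],
         "' epochs; cannot fit a two-class forest")
  }
  feats <- feature_columns(fm)
  x <- as.matrix(fm[, feats])
  occupied <- sort(unique(cluster_model$assignments[
    names(cluster_model$assignments) %in% unique(fm$recording_id)]))
  models <- vector("list", cluster_model$K)
  for (k in occupied) {
    w <- make_sample_weights(fm, cluster_model$assignments, k, boost)
    models[[k]] <- fit_forest(x, fm$label, params, weights = w)
  }
  structure(list(models = models, boost = boost, params = params,
                 feature_names = feats),
            class = "swrf_ensemble")
}

#' @export
print.swrf_ensemble <- function(x, ...) {
  cat(sprintf("<swrf_ensemble: %d forest(s), boost = %g, %d trees each>\n",
              sum(!vapply(x$models, is.null, logical(1L))), x$boost,
              x$params$num_trees))
  invisible(x)
}

#' Predict per-epoch suppression labels for one recording
#'
#' Routes the recording to its artifact cluster via [assign_cluster()] and
#' applies that cluster's forest (falling back to the nearest cluster that
#' has a model when the routed one is empty). Per epoch, the label is the
#' majority tree vote and the confidence is the vote fraction of the
#' predicted class.
#'
#' @param fm `epoch_feature_matrix` of the recording to predict.
#' @param map The recording's `artifact_feature_map` (for routing).
#' @param cluster_model Fitted `pges_cluster_model`.
#' @param ensemble Fitted `swrf_ensemble`.
#' @return An `epoch_predictions`: data frame with `epoch_start`, `label`,
#'   `confidence`, plus attributes `cluster` (route taken).
#' @export
predict_recording <- function(fm, map, cluster_model, ensemble) {
  k <- assign_cluster(map, cluster_model)
  if (is.null(ensemble$models[[k]])) {
    with_model <- which(!vapply(ensemble$models, is.null, logical(1L)))
    v <- as.numeric(map)
    d2 <- rowSums((cluster_model$centroids[with_model, , drop = FALSE] -
                     matrix(v, length(with_model), length(v),
                            byrow = TRUE))^2)
    k <- with_model[which.min(d2)]
  }
  x <- as.matrix(fm[, ensemble$feature_names])
  pr <- stats::predict(ensemble$models[[k]], data = x,
                       num.threads = 1L, verbose = FALSE)$predictions
  lab <- colnames(pr)[max.col(pr, ties.method = "first")]
  conf <- pr[cbind(seq_len(nrow(pr)), max.col(pr, ties.method = "first"))]
  out <- data.frame(epoch_start = fm$epoch_start, label = lab,
                    confidence = conf, stringsAsFactors = FALSE)
  class(out) <- c("epoch_predictions", "data.frame")
  attr(out, "cluster") <- k
  out
}

#' Confidence-based correction of epoch label sequences
#'
#' Absorbs implausible short state changes: any maximal run of identical
#' labels shorter than `min_run` epochs whose mean confidence is below
#' `conf_thresh` is flipped to the neighbouring label (the preceding run's
#' label; the first run takes the following run's label). The scan is
#' applied left to right and repeated until a fixpoint. Runs of length
#' `>= min_run`, and confident short runs, are never changed.
#'
#' @param preds An `epoch_predictions` data frame (or a character label
#'   vector plus `confidence`).
#' @param min_run Minimum plausible run length in epochs (default 3).
#' @param conf_thresh Mean-confidence threshold below which a short run may
#'   be flipped (default 0.8).
#' @return The input with a `corrected_label` column appended.
#' @export
correct_predictions <- function(preds, min_run = 3L, conf_thresh = 0.8) {
  lab <- preds$label
  conf <- preds$confidence
  repeat {
    r <- rle(lab)
    if (length(r$lengths) <= 1L) break
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    changed <- FALSE
    for (i in seq_along(r$lengths)) {
      if (r$lengths[i] >= min_run) next
      if (mean(conf[starts[i]:ends[i]]) >= conf_thresh) next
      neighbour <- if (i > 1L) lab[starts[i] - 1L] else lab[ends[i] + 1L]
      if (neighbour == r$values[i]) next
      lab[starts[i]:ends[i]] <- neighbour
      changed <- TRUE
      break  # restart: runs have merged
    }
    if (!changed) break
  }
  preds$corrected_label <- lab
  preds
}

#' Read the predicted PGES end time off a corrected label sequence
#'
#' The predicted end of PGES is the start time of the first non-suppression
#' epoch that follows at least one suppression epoch (epoch-aligned, whole
#' seconds). Returns `NA` with status `"no_suppression"` when no epoch was
#' labelled suppression; when suppression never ends, the window end is
#' returned with status `"unterminated"`.
#'
#' @param preds Output of [correct_predictions()] (uses `corrected_label`;
#'   falls back to `label`).
#' @param epoch_length Epoch length in seconds (default 1).
#' @return List with `p_end` (seconds or `NA`) and `status` (`"ok"`,
#'   `"no_suppression"`, or `"unterminated"`).
#' @export
detect_pges_end <- function(preds, epoch_length = 1) {
  lab <- preds$corrected_label
  if (is.null(lab)) lab <- preds$label
  starts <- preds$epoch_start
  sup <- lab == "suppression"
  if (!any(sup)) {
    return(list(p_end = NA_real_, status = "no_suppression"))
  }
  first_sup <- which(sup)[1L]
  after <- which(!sup & seq_along(lab) > first_sup)
  if (length(after) == 0L) {
    return(list(p_end = starts[length(starts)] + epoch_length,
                status = "unterminated"))
  }
  list(p_end = starts[after[1L]], status = "ok")
}
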