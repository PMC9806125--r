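# shared small training set (built once per file)
ds <- small_sim_dataset(n = 4, dur = 60, seed = 301, pges_range = c(10, 35))
cfg <- pipeline_config(K = 2, map_T = 60, num_trees = 50L, seed = 9)
feats <- precompute_features(ds, cfg)
all_fm <- do.call(rbind, feats$fms)
cl2 <- fit_kmeans(feats$maps, K = 2, seed = 9)

test_that("sample weights boost exactly the focal cluster's epochs", {
  asg <- c(a = 1L, b = 1L, c = 2L)
  fm <- data.frame(recording_id = rep(c("a", "b", "c"), c(20, 20, 60)))
  w <- make_sample_weights(fm, asg, focal_cluster = 1L, boost = 3)
  expect_equal(sum(w), 40 * 3 + 60)
  expect_true(all(make_sample_weights(fm, asg, 1L, boost = 1) == 1))
  # an empty focal cluster leaves all weights at 1
  expect_true(all(make_sample_weights(fm, asg, 5L, boost = 3) == 1))
  expect_error(make_sample_weights(
    data.frame(recording_id = "zzz"), asg, 1L, 2), "zzz")
})

test_that("the ensemble holds one forest per non-empty cluster", {
  ens <- train_ensemble(all_fm, cl2, params = rf_params(num_trees = 30L,
                                                        seed = 9),
                        boost = 2)
  occupied <- sort(unique(cl2$assignments))
  fitted <- which(!vapply(ens$models, is.null, logical(1L)))
  expect_equal(fitted, occupied)
})

test_that("single-class training data is rejected by name", {
  sup_only <- all_fm[all_fm$label == "suppression", ]
  expect_error(train_ensemble(sup_only, cl2), "non_suppression")
})

test_that("K = 1 with boost 1 is identical to one plain random forest", {
  one <- structure(list(K = 1L,
                        centroids = matrix(colMeans(t(vapply(
                          feats$maps, as.numeric,
                          numeric(length(feats$maps[[1L]]))))), nrow = 1L),
                        inertia = 0,
                        assignments = setNames(
                          rep(1L, length(feats$maps)), names(feats$maps)),
                        map_dim = dim(feats$maps[[1L]])),
                   class = "pges_cluster_model")
  prm <- rf_params(num_trees = 40L, seed = 77)
  ens <- train_ensemble(all_fm, one, params = prm, boost = 1)
  expect_length(Filter(Negate(is.null), ens$models), 1L)

  x <- as.matrix(all_fm[, pgesdetect:::feature_columns(all_fm)])
  y <- factor(all_fm$label, levels = c("suppression", "non_suppression"))
  plain <- ranger::ranger(x = x, y = y, num.trees = 40L, min.node.size = 1L,
                          probability = TRUE, seed = 77, num.threads = 1L,
                          verbose = FALSE)
  p_ens <- stats::predict(ens$models[[1L]], data = x,
                          num.threads = 1L)$predictions
  p_plain <- stats::predict(plain, data = x, num.threads = 1L)$predictions
  expect_identical(p_ens, p_plain)
})

test_that("prediction routes by cluster, is deterministic, and is confident", {
  ens <- train_ensemble(all_fm, cl2, params = rf_params(num_trees = 30L,
                                                        seed = 9),
                        boost = 2)
  id <- ds[[1L]]$recording$id
  pr <- predict_recording(feats$fms[[id]], feats$maps[[id]], cl2, ens)
  expect_true(all(pr$confidence >= 0.5 - 1e-9 & pr$confidence <= 1))
  expect_equal(attr(pr, "cluster"), unname(cl2$assignments[id]))
  pr2 <- predict_recording(feats$fms[[id]], feats$maps[[id]], cl2, ens)
  expect_identical(pr, pr2)

  # routing to an empty cluster falls back to the nearest fitted one
  holed <- ens
  holed$models[cl2$assignments[id]] <- list(NULL)
  pr3 <- predict_recording(feats$fms[[id]], feats$maps[[id]], cl2, holed)
  expect_false(attr(pr3, "cluster") == cl2$assignments[id])
})

test_that("low-confidence short runs are absorbed; confident ones survive", {
  mk <- function(labels, conf) {
    data.frame(epoch_start = seq_along(labels) - 1, label = labels,
               confidence = conf, stringsAsFactors = FALSE)
  }
  s <- "suppression"; i <- "non_suppression"
  lone <- mk(c(s, s, s, i, s, s), c(1, 1, 1, 0.55, 1, 1))
  out <- correct_predictions(lone, min_run = 2L, conf_thresh = 0.8)
  expect_equal(out$corrected_label, rep(s, 6))

  confident <- mk(c(s, s, s, i, s, s), c(1, 1, 1, 0.95, 1, 1))
  out2 <- correct_predictions(confident, min_run = 2L, conf_thresh = 0.8)
  expect_equal(out2$corrected_label, confident$label)

  homog <- mk(rep(s, 5), rep(0.6, 5))
  expect_equal(correct_predictions(homog)$corrected_label, rep(s, 5))
})

test_that("correction never touches runs at least min_run long", {
  s <- "suppression"; i <- "non_suppression"
  pgesdetect:::with_seed(41, {
    for (rep_i in 1:25) {
      labels <- sample(c(s, i), 40, replace = TRUE)
      conf <- runif(40, 0.5, 1)
      pr <- data.frame(epoch_start = 0:39, label = labels, confidence = conf,
                       stringsAsFactors = FALSE)
      out <- correct_predictions(pr, min_run = 3L, conf_thresh = 0.8)
      r <- rle(labels)
      ends <- cumsum(r$lengths)
      for (k in which(r$lengths >= 3L)) {
        idx <- (ends[k] - r$lengths[k] + 1L):ends[k]
        expect_identical(out$corrected_label[idx], labels[idx])
      }
    }
  })
})

test_that("the PGES end is the first resumption after suppression", {
  s <- "suppression"; i <- "non_suppression"
  mk <- function(lab) data.frame(epoch_start = seq_along(lab) - 1,
                                 label = lab, stringsAsFactors = FALSE)
  d1 <- detect_pges_end(mk(c(rep(s, 43), rep(i, 7))))
  expect_equal(d1$p_end, 43)
  expect_equal(d1$status, "ok")

  d2 <- detect_pges_end(mk(rep(i, 50)))
  expect_true(is.na(d2$p_end))
  expect_equal(d2$status, "no_suppression")

  d3 <- detect_pges_end(mk(rep(s, 300)))
  expect_equal(d3$p_end, 300)
  expect_equal(d3$status, "unterminated")
})
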