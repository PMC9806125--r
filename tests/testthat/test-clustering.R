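# small deterministic maps for clustering unit tests
fake_maps <- function(n, seed = 1, d = c(18L, 20L)) {
  pgesdetect:::with_seed(seed, {
    maps <- lapply(seq_len(n), function(i) {
      m <- matrix(abs(rnorm(prod(d))), d[1L], d[2L])
      structure(m, class = c("artifact_feature_map", "matrix", "array"))
    })
    names(maps) <- sprintf("r%02d", seq_len(n))
    maps
  })
}

test_that("K = n puts every recording in its own cluster with zero inertia", {
  maps <- fake_maps(5)
  cm <- fit_kmeans(maps, K = 5, seed = 2)
  expect_equal(sort(unique(cm$assignments)), 1:5)
  expect_equal(cm$inertia, 0, tolerance = 1e-8)
})

test_that("K greater than n is rejected and counts always sum to n", {
  maps <- fake_maps(6)
  expect_error(fit_kmeans(maps, K = 7), "exceeds")
  cm <- fit_kmeans(maps, K = 3, seed = 5)
  expect_equal(sum(table(cm$assignments)), 6L)
  expect_true(all(names(cm$assignments) == names(maps)))
})

test_that("converged inertia never exceeds the first Lloyd iteration's", {
  maps <- fake_maps(12, seed = 9)
  X <- t(vapply(maps, as.numeric, numeric(18 * 20)))
  pgesdetect:::with_seed(3, {
    init <- X[pgesdetect:::kmeanspp_init(X, 3L), ]
    one <- suppressWarnings(kmeans(X, centers = init, iter.max = 1L,
                                   algorithm = "Lloyd"))
    full <- suppressWarnings(kmeans(X, centers = init, iter.max = 100L,
                                    algorithm = "Lloyd"))
  })
  expect_lte(full$tot.withinss, one$tot.withinss + 1e-9)
})

test_that("fitting is deterministic given the seed", {
  maps <- fake_maps(10, seed = 4)
  a <- fit_kmeans(maps, K = 3, seed = 11)
  b <- fit_kmeans(maps, K = 3, seed = 11)
  expect_identical(a$assignments, b$assignments)
  expect_equal(a$centroids, b$centroids)
})

test_that("assignment picks the nearest centroid with low-index ties", {
  maps <- fake_maps(6, seed = 7)
  cm <- fit_kmeans(maps, K = 3, seed = 1)
  # a map equal to a centroid routes to it
  m3 <- structure(matrix(cm$centroids[3L, ], 18L, 20L),
                  class = c("artifact_feature_map", "matrix", "array"))
  expect_equal(assign_cluster(m3, cm), 3L)
  # equidistant synthetic model: ties break to the lowest index
  tie_model <- structure(list(K = 2L,
                              centroids = rbind(c(1, 0), c(-1, 0)),
                              inertia = 0,
                              assignments = c(a = 1L, b = 2L),
                              map_dim = c(1L, 2L)),
                         class = "pges_cluster_model")
  expect_equal(assign_cluster(matrix(c(0, 5), 1L), tie_model), 1L)
  expect_error(assign_cluster(matrix(0, 3L, 3L), cm), "expects")
})

test_that("training maps keep their own assignment after convergence", {
  maps <- fake_maps(10, seed = 13)
  cm <- fit_kmeans(maps, K = 3, seed = 21)
  routed <- vapply(maps, assign_cluster, integer(1L), model = cm)
  expect_identical(unname(routed), unname(cm$assignments))
})

test_that("archetype structure is recovered exactly at high intensity", {
  archs <- list(
    artifact_archetype("temporal", 1:8, "breathing", 5, 20, 300),
    artifact_archetype("parasagittal", 9:16, "movement", 5, 20, 300))
  ds <- simulate_dataset(10, archs, seed = 47,
                         params = simulation_params(duration = 40),
                         pges_range = c(5, 12))
  maps <- lapply(ds, function(d) {
    artifact_feature_map(bandpass(d$recording, 0.5, 30), T_seconds = 40)
  })
  names(maps) <- vapply(ds, function(d) d$recording$id, "")
  cm <- fit_kmeans(maps, K = 2, seed = 3)
  tags <- vapply(ds, `[[`, "", "archetype")
  tab <- table(tags, cm$assignments)
  # exact recovery up to label permutation
  expect_equal(sort(apply(tab, 1L, max)), sort(rowSums(tab)))
})

test_that("cluster models round-trip through JSON", {
  maps <- fake_maps(6, seed = 19)
  cm <- fit_kmeans(maps, K = 2, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_cluster_model(cm, path)
  back <- read_cluster_model(path)
  expect_equal(back$K, cm$K)
  expect_equal(back$centroids, cm$centroids, tolerance = 1e-12)
  expect_identical(back$assignments, cm$assignments)
})
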