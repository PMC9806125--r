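#' K-means clustering of recordings by artifact feature maps
#'
#' Groups recordings whose low-frequency Hilbert-amplitude maps show similar
#' spatiotemporal artifact patterns. Maps are flattened to vectors (they are
#' already normalized per recording) and clustered by Lloyd iterations from
#' k-means++ starting centers; `restarts` independent starts are run and the
#' model with the lowest inertia (total within-cluster sum of squares) is
#' kept. Deterministic given `seed`.
#'
#' @param maps Named list of `artifact_feature_map` objects (names =
#'   recording ids), all the same shape.
#' @param K Number of clusters, `1 <= K <= length(maps)`.
#' @param seed Integer RNG seed.
#' @param restarts Number of k-means++ restarts (default 10).
#' @param iter_max Lloyd iteration cap per start (default 100).
#' @return A `pges_cluster_model`: list with `K`, `centroids` (K x D),
#'   `inertia`, `assignments` (named integer vector, recording id ->
#'   cluster), `map_dim`.
#' @export
fit_kmeans <- function(maps, K, seed = 1L, restarts = 10L, iter_max = 100L) {
  n <- length(maps)
  if (K > n) stop("K = ", K, " exceeds the number of recordings (", n, ")")
  stopifnot(K >= 1L)
  dims <- unique(lapply(maps, dim))
  if (length(dims) != 1L) stop("artifact maps have inconsistent shapes")
  X <- t(vapply(maps, as.numeric, numeric(prod(dims[[1L]]))))
  ids <- names(maps)
  if (is.null(ids)) ids <- paste0("rec", seq_len(n))

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      centers <- X[kmeanspp_init(X, K), , drop = FALSE]
      km <- suppressWarnings(
        kmeans(X, centers = centers, iter.max = iter_max,
               algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  structure(list(K = K,
                 centroids = unname(best$centers),
                 inertia = best$tot.withinss,
                 assignments = setNames(as.integer(best$cluster), ids),
                 map_dim = dims[[1L]]),
            class = "pges_cluster_model")
}

# k-means++ seeding: returns K row indices of X
kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  centers <- sample.int(n, 1L)
  if (K == 1L) return(centers)
  d2 <- rowSums((X - matrix(X[centers, ], n, ncol(X), byrow = TRUE))^2)
  for (k in 2L:K) {
    if (all(d2 == 0)) {
      centers <- c(centers, sample(setdiff(seq_len(n), centers), 1L))
    } else {
      centers <- c(centers, sample.int(n, 1L, prob = d2))
    }
    dk <- rowSums((X - matrix(X[centers[k], ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, dk)
  }
  centers
}

#' @export
print.pges_cluster_model <- function(x, ...) {
  cat(sprintf("<pges_cluster_model: K = %d, n = %d, inertia = %.4g>\n",
              x$K, length(x$assignments), x$inertia))
  invisible(x)
}

#' Assign a recording to its nearest artifact cluster
#'
#' Routes an unseen recording's artifact map to the fitted cluster with the
#' nearest centroid (Euclidean distance on the flattened map). Ties go to
#' the lowest cluster index.
#'
#' @param map An `artifact_feature_map` with the model's map shape.
#' @param model A `pges_cluster_model` from [fit_kmeans()].
#' @return Integer cluster index in `1..K`.
#' @export
assign_cluster <- function(map, model) {
  v <- as.numeric(map)
  if (length(v) != ncol(model$centroids)) {
    stop("map has ", length(v), " values; model expects ",
         ncol(model$centroids))
  }
  d2 <- rowSums((model$centroids -
                   matrix(v, model$K, length(v), byrow = TRUE))^2)
  which.min(d2)  # which.min takes the first (lowest index) on ties
}

#' Serialize / restore a cluster model as JSON
#' @param model A `pges_cluster_model`.
#' @param path JSON file path.
#' @return `path` invisibly (write); a `pges_cluster_model` (read).
#' @export
write_cluster_model <- function(model, path) {
  jsonlite::write_json(list(K = model$K,
                            centroids = model$centroids,
                            inertia = model$inertia,
                            assignments = as.list(model$assignments),
                            map_dim = model$map_dim),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cent <- j$centroids
  if (!is.matrix(cent)) cent <- matrix(unlist(cent), nrow = j$K, byrow = TRUE)
  structure(list(K = as.integer(j$K),
                 centroids = cent,
                 inertia = j$inertia,
                 assignments = setNames(as.integer(unlist(j$assignments)),
                                        names(j$assignments)),
                 map_dim = as.integer(j$map_dim)),
            class = "pges_cluster_model")
}
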