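#' Cluster explanation-weighted features
#'
#' The final discovery step: reduce penultimate-layer features of the
#' explanation-weighted images with [reduce_features()], choose K by the
#' silhouette criterion via [select_k()] (or use a fixed K), and score the
#' resulting partition with the silhouette coefficient, the Davies-Bouldin
#' index and — when ground-truth subtypes are supplied — the Rand index.
#'
#' @param features Numeric matrix of raw penultimate features, one row per
#'   image classified pathological.
#' @param k Fixed number of clusters; `NULL` (default) selects K over
#'   `k_range` by maximum silhouette.
#' @param k_range Candidate K values scanned when `k` is `NULL`.
#' @param truth Optional vector of true subtype labels for the same rows.
#' @param seed Integer seed for the clustering.
#' @param n_restarts K-means restarts.
#' @param target_dim,variance,max_dim Passed to [reduce_features()].
#' @param l2_normalize Scale each feature row to unit length (see
#'   [l2_normalize_rows()]) before reduction; held-out rows passed to
#'   [assign_unseen()] are treated identically. On by default: it removes the
#'   per-image explanation-strength nuisance that otherwise dominates
#'   Euclidean distances between weighted-image features.
#' @param ids Optional row identifiers kept alongside the labels.
#' @return An `xw_clusters` object: `k`, `labels`, `centroids` (in reduced
#'   space), `sizes`, `silhouette`, `davies_bouldin`, `rand` (or `NA`),
#'   `metrics` (per-K table when K was selected), `reducer`, `ids`.
#' @export
cluster_weighted <- function(features, k = NULL, k_range = 2:6, truth = NULL,
                             seed = 1L, n_restarts = 10L, target_dim = NULL,
                             variance = 0.9, max_dim = 32L,
                             l2_normalize = TRUE, ids = NULL) {
  features <- as.matrix(features)
  if (nrow(features) < 3) {
    stop("need at least 3 pathological images to cluster", call. = FALSE)
  }
  if (l2_normalize) features <- l2_normalize_rows(features)
  reducer <- reduce_features(features, target_dim = target_dim,
                             variance = variance, max_dim = max_dim)
  x <- reducer$scores
  metrics <- NULL
  if (is.null(k)) {
    sel <- select_k(x, k_min = min(k_range), k_max = min(max(k_range), nrow(x) - 1),
                    seed = seed, n_restarts = n_restarts)
    k <- sel$k
    fit <- sel$result
    metrics <- sel$metrics
  } else {
    fit <- xw_kmeans(x, k, seed = seed, n_restarts = n_restarts)
  }
  rand <- if (!is.null(truth)) rand_index(truth, fit$labels) else NA_real_
  structure(
    list(k = k, labels = fit$labels, centroids = fit$centroids,
         sizes = fit$sizes, inertia = fit$inertia,
         silhouette = silhouette_score(x, fit$labels),
         davies_bouldin = davies_bouldin(x, fit$labels),
         rand = rand, metrics = metrics, reducer = reducer,
         l2_normalize = l2_normalize, scores = x, truth = truth,
         ids = ids %||% seq_len(nrow(features))),
    class = "xw_clusters"
  )
}

#' Assign held-out images to existing clusters
#'
#' Projects raw penultimate features of unseen explanation-weighted images
#' through the fitted reducer and assigns each to the nearest centroid
#' (Euclidean; ties break toward the lowest-index centroid). This is the
#' "classification test" on images the clustering never saw.
#'
#' @param clusters An `xw_clusters` from [cluster_weighted()].
#' @param features Raw feature matrix of the held-out images (same columns as
#'   the features the clusters were fitted on), or an already-reduced matrix
#'   with `reduce = FALSE`.
#' @param reduce Project through the stored reducer first?
#' @return Integer cluster labels in `1..k`.
#' @export
assign_unseen <- function(clusters, features, reduce = TRUE) {
  stopifnot(inherits(clusters, "xw_clusters"))
  x <- as.matrix(features)
  if (reduce) {
    if (isTRUE(clusters$l2_normalize)) x <- l2_normalize_rows(x)
    x <- project_features(clusters$reducer, x)
  }
  if (ncol(x) != ncol(clusters$centroids)) {
    stop("feature dimension does not match the centroids", call. = FALSE)
  }
  d2 <- pmax(sq_dist_to(x, clusters$centroids), 0)
  max.col(-d2, ties.method = "first")
}

#' @export
print.xw_clusters <- function(x, ...) {
  cat("<xw_clusters> K = ", x$k, " over ", length(x$labels), " images; ",
      "sizes [", paste(x$sizes, collapse = ", "), "]\n",
      "  silhouette ", signif(x$silhouette, 4),
      ", Davies-Bouldin ", signif(x$davies_bouldin, 4), sep = "")
  if (!is.na(x$rand)) cat(", Rand vs truth ", signif(x$rand, 4), sep = "")
  cat("\n")
  invisible(x)
}

#' Tidy per-image cluster assignments
#'
#' @param x An `xw_clusters`.
#' @param ... Unused.
#' @return Tibble with one row per clustered image: `id`, `cluster`, the
#'   reduced coordinates `dim1`/`dim2` (when available) and `truth` if known.
#' @export
tidy.xw_clusters <- function(x, ...) {
  out <- tibble::tibble(id = x$ids, cluster = factor(x$labels))
  if (ncol(x$scores) >= 1) out$dim1 <- x$scores[, 1]
  if (ncol(x$scores) >= 2) out$dim2 <- x$scores[, 2]
  if (!is.null(x$truth)) out$truth <- x$truth
  out
}

#' One-row clustering summary
#'
#' @inheritParams tidy.xw_clusters
#' @return Tibble with `k`, `n`, `silhouette`, `davies_bouldin`, `rand`,
#'   `inertia` and the reduced dimension used.
#' @export
glance.xw_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$labels), silhouette = x$silhouette,
                 davies_bouldin = x$davies_bouldin, rand = x$rand,
                 inertia = x$inertia, reduced_dim = x$reducer$k,
                 var_explained = x$reducer$var_explained)
}

#' @export
#' @rdname autoplot_xwclust
autoplot.xw_clusters <- function(object, ...) {
  df <- tidy(object)
  if (!all(c("dim1", "dim2") %in% names(df))) {
    stop("need at least 2 reduced dimensions to plot", call. = FALSE)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "component 1", y = "component 2",
                  title = sprintf("Explanation-weighted clusters (K = %d)",
                                  object$k)) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
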