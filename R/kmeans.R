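#' K-means with K-means++ initialization
#'
#' Lloyd's algorithm from a K-means++ start (each further centroid drawn with
#' probability proportional to the squared distance to the nearest centroid
#' chosen so far), run `n_restarts` times with the best run — lowest inertia,
#' the within-cluster sum of squared distances — kept. Ties in point
#' assignment go to the lowest-index centroid; a cluster that empties is
#' reseeded at the point farthest from its centroid set. Inertia is checked to
#' be non-increasing across Lloyd iterations on every run.
#'
#' @param x Numeric matrix, rows = points.
#' @param k Number of clusters (2 <= k <= rows).
#' @param seed Integer seed.
#' @param n_restarts Independent seeded restarts.
#' @param max_iter Lloyd iteration cap per run.
#' @return An `xw_kmeans`: list with `labels` (1..k), `centroids`, `inertia`,
#'   `inertia_trace` of the winning run, `k`, `sizes`.
#' @export
xw_kmeans <- function(x, k, seed = 1L, n_restarts = 10L, max_iter = 100L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > n) stop("k cannot exceed the number of points", call. = FALSE)
  best <- NULL
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_restarts)) {
      run <- kmeans_once(x, k, max_iter)
      if (is.null(best) || run$inertia < best$inertia - 1e-12) best <- run
    }
  })
  structure(c(best, list(k = as.integer(k),
                         sizes = tabulate(best$labels, nbins = k))),
            class = "xw_kmeans")
}

sq_dist_to <- function(x, centroids) {
  # n x k matrix of squared Euclidean distances
  cross <- x %*% t(centroids)
  outer(rowSums(x^2), rep(1, nrow(centroids))) -
    2 * cross + outer(rep(1, nrow(x)), rowSums(centroids^2))
}

kmeans_once <- function(x, k, max_iter) {
  n <- nrow(x)
  # K-means++ seeding
  centroids <- x[sample.int(n, 1), , drop = FALSE]
  while (nrow(centroids) < k) {
    d2 <- apply(sq_dist_to(x, centroids), 1, min)
    d2 <- pmax(d2, 0)
    pick <- if (sum(d2) <= 0) sample.int(n, 1) else sample.int(n, 1, prob = d2)
    centroids <- rbind(centroids, x[pick, , drop = FALSE])
  }
  labels <- integer(n)
  trace <- numeric(0)
  prev_inertia <- Inf
  for (it in seq_len(max_iter)) {
    d2 <- pmax(sq_dist_to(x, centroids), 0)
    new_labels <- max.col(-d2, ties.method = "first")
    inertia <- sum(d2[cbind(seq_len(n), new_labels)])
    if (inertia > prev_inertia + 1e-8 * (1 + prev_inertia)) {
      stop("internal error: inertia increased across a Lloyd iteration",
           call. = FALSE)
    }
    trace <- c(trace, inertia)
    prev_inertia <- inertia
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (j in seq_len(k)) {
      members <- labels == j
      if (any(members)) {
        centroids[j, ] <- colMeans(x[members, , drop = FALSE])
      } else {
        far <- which.max(apply(pmax(sq_dist_to(x, centroids), 0), 1, min))
        centroids[j, ] <- x[far, ]
      }
    }
  }
  d2 <- pmax(sq_dist_to(x, centroids), 0)
  labels <- max.col(-d2, ties.method = "first")
  list(labels = labels, centroids = centroids,
       inertia = sum(d2[cbind(seq_len(n), labels)]), inertia_trace = trace)
}

#' Silhouette-guided choice of the number of clusters
#'
#' Runs [xw_kmeans()] for every K in `k_min:k_max` and picks the K with the
#' highest mean silhouette, breaking ties toward the smaller K (parsimony).
#' The full per-K metric table (silhouette, Davies-Bouldin, inertia) is
#' returned so weak structure — silhouettes low everywhere — is visible to
#' the caller rather than hidden behind the argmax.
#'
#' @param x Numeric matrix, rows = points.
#' @param k_min,k_max Range of K to scan (`2 <= k_min`,
#'   `k_max <= rows - 1`).
#' @param seed Integer seed (each K uses a seed derived from it).
#' @param n_restarts Restarts per K.
#' @return List with `k` (the selected K), `metrics` (tibble: k, silhouette,
#'   davies_bouldin, inertia) and `result`, the winning `xw_kmeans`.
#' @export
select_k <- function(x, k_min = 2L, k_max = 6L, seed = 1L, n_restarts = 10L) {
  x <- as.matrix(x)
  if (k_min < 2) stop("k_min must be >= 2", call. = FALSE)
  if (k_max < k_min) stop("k_max must be >= k_min", call. = FALSE)
  if (k_max > nrow(x) - 1) stop("k_max must be <= n - 1", call. = FALSE)
  ks <- k_min:k_max
  runs <- lapply(ks, function(k) {
    xw_kmeans(x, k, seed = as.integer(seed) + k, n_restarts = n_restarts)
  })
  metrics <- tibble::tibble(
    k = ks,
    silhouette = vapply(runs, function(r) silhouette_score(x, r$labels),
                        numeric(1)),
    davies_bouldin = vapply(runs, function(r) davies_bouldin(x, r$labels),
                            numeric(1)),
    inertia = vapply(runs, function(r) r$inertia, numeric(1))
  )
  pick <- which.max(metrics$silhouette)  # which.max takes the first maximum
  list(k = ks[pick], metrics = metrics, result = runs[[pick]])
}
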