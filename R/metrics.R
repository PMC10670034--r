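#' Rand index between two labelings
#'
#' The fraction of the `n(n-1)/2` point pairs on which the two labelings
#' agree (both place the pair together, or both apart). It is invariant to
#' relabeling either side, which is what makes it usable for scoring clusters
#' against ground truth. This is the plain (unadjusted) index in `[0, 1]`.
#'
#' @param labels_a,labels_b Equal-length label vectors (any atomic type),
#'   length >= 2.
#' @param adjusted Return the chance-corrected (adjusted) variant instead.
#' @return A number in `[0, 1]` (the adjusted variant can be negative).
#' @export
rand_index <- function(labels_a, labels_b, adjusted = FALSE) {
  if (length(labels_a) != length(labels_b)) {
    stop("labelings must have equal length", call. = FALSE)
  }
  n <- length(labels_a)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  tab <- table(labels_a, labels_b)
  ch2 <- function(m) sum(m * (m - 1) / 2)
  a <- ch2(tab)                      # pairs together in both
  ra <- ch2(rowSums(tab))
  cb <- ch2(colSums(tab))
  total <- n * (n - 1) / 2
  if (!adjusted) {
    return((total + 2 * a - ra - cb) / total)
  }
  expected <- ra * cb / total
  maxi <- (ra + cb) / 2
  if (maxi == expected) return(0)
  (a - expected) / (maxi - expected)
}

#' Mean silhouette coefficient
#'
#' For each point, `a` is its mean distance to the other members of its own
#' cluster and `b` the smallest mean distance to the members of any other
#' cluster; its silhouette is `(b - a) / max(a, b)`. Points in singleton
#' clusters score 0. The mean over all points lies in `[-1, 1]`; large values
#' mean tight, well-separated clusters.
#'
#' @param x Numeric matrix (rows = points) or a `dist` object.
#' @param labels Cluster labels, at least two distinct, each non-empty.
#' @return Mean silhouette over all points.
#' @export
silhouette_score <- function(x, labels) {
  d <- if (inherits(x, "dist")) as.matrix(x) else as.matrix(stats::dist(x))
  labels <- as.vector(labels)
  if (length(labels) != nrow(d)) {
    stop("labels must match the number of points", call. = FALSE)
  }
  cl <- unique(labels)
  if (length(cl) < 2) stop("silhouette needs at least 2 clusters", call. = FALSE)
  sizes <- table(labels)
  s <- vapply(seq_along(labels), function(i) {
    own <- labels[i]
    if (sizes[[as.character(own)]] == 1) return(0)
    a <- sum(d[i, labels == own]) / (sizes[[as.character(own)]] - 1)
    b <- min(vapply(setdiff(cl, own),
                    function(k) mean(d[i, labels == k]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Davies-Bouldin index
#'
#' For each cluster, the within-cluster scatter is the mean Euclidean distance
#' of its members to the centroid; the index averages, over clusters, the
#' worst ratio `(s_i + s_j) / d(c_i, c_j)` against any other cluster. Lower
#' is better; 0 means point-mass clusters.
#'
#' @param x Numeric matrix (rows = points).
#' @param labels Cluster labels, at least two distinct.
#' @return A non-negative number.
#' @export
davies_bouldin <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.vector(labels)
  cl <- unique(labels)
  if (length(cl) < 2) stop("Davies-Bouldin needs at least 2 clusters",
                           call. = FALSE)
  cent <- do.call(rbind, lapply(cl, function(k) {
    colMeans(x[labels == k, , drop = FALSE])
  }))
  scatter <- vapply(seq_along(cl), function(i) {
    xi <- x[labels == cl[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2, cent[i, ])^2)))
  }, numeric(1))
  K <- length(cl)
  ratios <- vapply(seq_len(K), function(i) {
    max(vapply(setdiff(seq_len(K), i), function(j) {
      dij <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      (scatter[i] + scatter[j]) / dij
    }, numeric(1)))
  }, numeric(1))
  mean(ratios)
}
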