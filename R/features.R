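#' SVD dimensionality reduction of feature matrices
#'
#' Columns are centered, the singular value decomposition of the centered
#' matrix is taken, and rows are projected onto the leading right singular
#' vectors. The number of components is either `target_dim` or the smallest
#' number explaining at least `variance` of the total variance, capped at
#' `min(max_dim, n_rows - 1, n_cols)`. Component signs are fixed by a
#' canonical convention (the loading of largest magnitude is positive), so
#' the reduction is fully deterministic.
#'
#' @param x Numeric matrix, rows = images, columns = raw features.
#' @param target_dim Optional fixed number of components.
#' @param variance Variance fraction to retain when `target_dim` is `NULL`.
#' @param max_dim Upper cap on the number of retained components.
#' @return An `xw_reducer`: list with `scores` (reduced matrix), `rotation`,
#'   `center`, `k` and `var_explained` (cumulative fraction retained).
#' @export
reduce_features <- function(x, target_dim = NULL, variance = 0.9,
                            max_dim = 32L) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to reduce", call. = FALSE)
  if (!all(is.finite(x))) stop("features must be finite", call. = FALSE)
  cap <- min(max_dim, nrow(x) - 1L, ncol(x))
  if (!is.null(target_dim)) {
    if (target_dim >= nrow(x) && target_dim >= ncol(x)) {
      stop("target_dim must be below the matrix dimensions", call. = FALSE)
    }
    if (target_dim < 1) stop("target_dim must be >= 1", call. = FALSE)
  }
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  sv <- svd(xc)
  ev <- sv$d^2
  frac <- if (sum(ev) > 0) cumsum(ev) / sum(ev) else rep(1, length(ev))
  k <- if (!is.null(target_dim)) as.integer(target_dim)
       else max(1L, min(cap, which(frac >= variance)[1]))
  k <- min(k, length(sv$d))
  rot <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  structure(
    list(scores = xc %*% rot, rotation = rot, center = center, k = k,
         var_explained = frac[k]),
    class = "xw_reducer"
  )
}

#' Scale feature rows to unit Euclidean length
#'
#' Explanation-weighted images differ not only in *which* characteristic they
#' contain but in how strongly the explanation weighted it; that overall
#' strength scales the whole penultimate feature vector. Normalizing each row
#' to unit length keeps the activation pattern (the characteristic) and
#' discards the strength nuisance. Zero rows are left unchanged.
#'
#' @param x Numeric matrix, rows = images.
#' @return Matrix with unit-norm rows.
#' @export
l2_normalize_rows <- function(x) {
  x <- as.matrix(x)
  n <- sqrt(rowSums(x^2))
  x / pmax(n, 1e-12)
}

#' Project new rows with a fitted reducer
#'
#' @param reducer An [reduce_features()] result.
#' @param x Matrix with the same raw feature columns.
#' @return Reduced `nrow(x) x k` matrix.
#' @export
project_features <- function(reducer, x) {
  stopifnot(inherits(reducer, "xw_reducer"))
  x <- as.matrix(x)
  if (ncol(x) != length(reducer$center)) {
    stop("feature dimension does not match the reducer", call. = FALSE)
  }
  sweep(x, 2, reducer$center) %*% reducer$rotation
}
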