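# Independent brute-force oracles used to validate the implementation.

# Occlusion attribution by direct enumeration: for every pixel, average
# f(I) - f(occluded) over every patch containing it.
brute_force_attribution <- function(classifier, image, grid, C = 128 / 255) {
  H <- dim(image)[1]
  W <- dim(image)[2]
  f0 <- classifier(image)
  out <- matrix(0, H, W)
  for (y in seq_len(H)) {
    for (x in seq_len(W)) {
      drops <- c()
      for (i in seq_len(grid$n)) {
        r <- grid$rects[i, ]
        if (y >= r$top && y <= r$top + r$height - 1 &&
            x >= r$left && x <= r$left + r$width - 1) {
          occ <- image
          occ[r$top:(r$top + r$height - 1),
              r$left:(r$left + r$width - 1), ] <- C
          drops <- c(drops, f0 - classifier(occ))
        }
      }
      out[y, x] <- mean(drops)
    }
  }
  out
}

# Per-point silhouette by the definition, one point at a time.
brute_force_silhouette <- function(x, labels) {
  d <- as.matrix(stats::dist(x))
  s <- numeric(length(labels))
  for (i in seq_along(labels)) {
    own <- labels[i]
    mine <- which(labels == own & seq_along(labels) != i)
    if (length(mine) == 0) { s[i] <- 0; next }
    a <- mean(d[i, mine])
    b <- Inf
    for (k in setdiff(unique(labels), own)) {
      b <- min(b, mean(d[i, labels == k]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Davies-Bouldin by direct looping over the definition.
brute_force_davies_bouldin <- function(x, labels) {
  x <- as.matrix(x)
  cl <- unique(labels)
  K <- length(cl)
  cent <- list()
  scat <- numeric(K)
  for (i in seq_len(K)) {
    xi <- x[labels == cl[i], , drop = FALSE]
    cent[[i]] <- colMeans(xi)
    scat[i] <- mean(apply(xi, 1, function(r) sqrt(sum((r - cent[[i]])^2))))
  }
  total <- 0
  for (i in seq_len(K)) {
    worst <- -Inf
    for (j in seq_len(K)) {
      if (i == j) next
      dij <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      worst <- max(worst, (scat[i] + scat[j]) / dij)
    }
    total <- total + worst
  }
  total / K
}

# Plain Rand index by enumerating all pairs.
brute_force_rand <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
    }
  }
  agree / (n * (n - 1) / 2)
}
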