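test_that("explanation weighting implements I * max(Y, 0) per channel", {
  img <- withr::with_seed(1, array(runif(16 * 16 * 3), c(16, 16, 3)))
  ones <- matrix(1, 16, 16)
  expect_identical(weight_image(img, ones), img)
  expect_true(all(weight_image(img, matrix(0, 16, 16)) == 0))
  expect_true(all(weight_image(img, matrix(-0.7, 16, 16)) == 0))

  # a binary mask cuts the shape out onto black
  msk <- matrix(0, 16, 16)
  msk[4:9, 5:12] <- 1
  out <- weight_image(img, msk)
  for (ch in 1:3) {
    expect_equal(out[, , ch][msk == 1], img[, , ch][msk == 1])
    expect_true(all(out[, , ch][msk == 0] == 0))
  }

  im <- importance_map(msk - 0.5, "smoothed")
  out2 <- weight_image(img, im)
  expect_true(all(out2 <= img + 1e-15))
  expect_true(all(out2[, , 1][msk == 0] == 0))

  expect_error(weight_image(img, matrix(1, 8, 8)), "shape")
})

test_that("weighting is monotone in the explanation", {
  img <- withr::with_seed(2, array(runif(12 * 12 * 3), c(12, 12, 3)))
  v <- withr::with_seed(3, matrix(runif(144, -1, 1), 12, 12))
  base <- weight_image(img, v)
  for (i in 1:10) {
    v2 <- v
    idx <- withr::with_seed(i, sample(144, 5))
    v2[idx] <- pmin(v2[idx] + withr::with_seed(i + 50, runif(5, 0, 0.5)), 1)
    expect_true(all(weight_image(img, v2) >= base - 1e-15))
  }
})

test_that("SVD reduction captures rank, separates clusters and preserves distances", {
  # rank-1 matrix: one component explains all variance
  base <- withr::with_seed(4, rnorm(6))
  x1 <- outer(c(1, 2, 3, 4), base)
  r1 <- reduce_features(x1, target_dim = 1)
  expect_equal(r1$var_explained, 1.0)

  # two clusters along the first axis split by the sign of component 1
  x2 <- rbind(matrix(rep(c(1, 0, 0, 0), 5), 5, 4, byrow = TRUE),
              matrix(rep(c(-1, 0, 0, 0), 5), 5, 4, byrow = TRUE)) +
    withr::with_seed(5, matrix(rnorm(40, sd = 1e-3), 10, 4))
  r2 <- reduce_features(x2, target_dim = 1)
  expect_true(all(sign(r2$scores[1:5]) == sign(r2$scores[1])))
  expect_true(all(sign(r2$scores[6:10]) == -sign(r2$scores[1])))

  # dropping the smallest singular direction perturbs distances at most by
  # twice that singular value
  x3 <- withr::with_seed(6, matrix(rnorm(8 * 5), 8, 5))
  r3 <- reduce_features(x3, target_dim = 4)
  d_full <- as.matrix(stats::dist(sweep(x3, 2, colMeans(x3))))
  d_red <- as.matrix(stats::dist(r3$scores))
  smin <- min(svd(sweep(x3, 2, colMeans(x3)))$d)
  expect_lt(max(abs(d_full - d_red)), 2 * smin + 1e-12)

  expect_error(reduce_features(x3[1, , drop = FALSE]), "at least 2")
  expect_error(reduce_features(x3, target_dim = 10), "below")
})

test_that("reduction is deterministic and projection matches training scores", {
  x <- withr::with_seed(7, matrix(rnorm(20 * 6), 20, 6))
  r1 <- reduce_features(x, variance = 0.9)
  r2 <- reduce_features(x, variance = 0.9)
  expect_identical(r1$scores, r2$scores)
  expect_equal(project_features(r1, x), r1$scores)
})

test_that("K-means recovers separated clouds and minimizes the toy instance", {
  # two well-separated clouds
  x <- rbind(withr::with_seed(8, matrix(rnorm(40, 0, 0.1), 20, 2)),
             withr::with_seed(9, matrix(rnorm(40, 5, 0.1), 20, 2)))
  truth <- rep(1:2, each = 20)
  km <- xw_kmeans(x, 2, seed = 1)
  expect_equal(rand_index(truth, km$labels), 1.0)

  # K = n: every point its own centroid, inertia 0
  x4 <- withr::with_seed(10, matrix(rnorm(8), 4, 2))
  expect_equal(xw_kmeans(x4, 4, seed = 1)$inertia, 0)

  # 1-D instance with a known optimum, verified by enumerating partitions
  x1 <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  km1 <- xw_kmeans(x1, 2, seed = 3)
  expect_equal(km1$inertia, 0.01)
  expect_equal(km1$labels[1], km1$labels[2])
  expect_equal(km1$labels[3], km1$labels[4])
  best <- Inf
  for (mask in 1:(2^4 - 2)) {
    grp <- as.logical(bitwAnd(mask, 2^(0:3)))
    if (all(grp) || all(!grp)) next
    inertia <- sum((x1[grp] - mean(x1[grp]))^2) +
      sum((x1[!grp] - mean(x1[!grp]))^2)
    best <- min(best, inertia)
  }
  expect_equal(km1$inertia, best)
})

test_that("K-means agrees with the reference implementation on easy data", {
  x <- rbind(withr::with_seed(11, matrix(rnorm(60, 0, 0.2), 30, 2)),
             withr::with_seed(12, matrix(rnorm(60, 4, 0.2), 30, 2)))
  ours <- xw_kmeans(x, 2, seed = 5)
  ref <- withr::with_seed(5, stats::kmeans(x, 2, nstart = 10))
  expect_equal(ours$inertia, ref$tot.withinss, tolerance = 1e-8)
  expect_equal(rand_index(ours$labels, ref$cluster), 1.0)
})

test_that("the Lloyd inertia trace is non-increasing", {
  x <- withr::with_seed(13, matrix(rnorm(200), 100, 2))
  for (k in c(2, 5)) {
    km <- xw_kmeans(x, k, seed = 2, n_restarts = 3)
    expect_true(all(diff(km$inertia_trace) <= 1e-9))
  }
})

test_that("silhouette-guided selection finds the true number of blobs", {
  centers <- rbind(c(0, 0), c(8, 0), c(0, 8))
  x <- do.call(rbind, lapply(1:3, function(i) {
    withr::with_seed(i + 20,
                     matrix(rnorm(30, sd = 0.3), 15, 2) +
                       rep(centers[i, ], each = 15))
  }))
  sel <- select_k(x, 2, 6, seed = 1)
  expect_equal(sel$k, 3)
  expect_equal(sel$metrics$k, 2:6)
  expect_equal(sel$metrics$silhouette[2], max(sel$metrics$silhouette))

  # a single tight blob (isotropic, 10-d) has weak structure at every K
  lone <- withr::with_seed(30, matrix(rnorm(300, sd = 0.1), 30, 10))
  sel2 <- select_k(lone, 2, 4, seed = 1)
  expect_true(all(sel2$metrics$silhouette < 0.25))

  expect_error(select_k(x, 1, 4), "k_min")
  expect_error(select_k(x, 4, 2), "k_max")
})

test_that("Rand index matches hand counts and the reference implementation", {
  expect_equal(rand_index(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1.0)
  expect_equal(rand_index(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1.0)
  expect_equal(rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1)), 1 / 3)
  expect_error(rand_index(c(1, 2), c(1, 2, 3)), "equal length")

  skip_if_not_installed("e1071")
  for (s in 1:50) {
    n <- withr::with_seed(s, sample(5:25, 1))
    a <- withr::with_seed(s + 100, sample(1:4, n, replace = TRUE))
    b <- withr::with_seed(s + 200, sample(1:3, n, replace = TRUE))
    expect_equal(rand_index(a, b),
                 e1071::classAgreement(table(a, b))$rand, tolerance = 1e-9)
    expect_equal(rand_index(a, b), brute_force_rand(a, b), tolerance = 1e-9)
  }
})

test_that("silhouette matches hand values and brute force", {
  # duplicated point-mass clusters: a = 0 -> silhouette 1
  pm <- matrix(c(0, 0, 10, 10), 4, 1)
  expect_equal(silhouette_score(pm, c(1, 1, 2, 2)), 1.0)
  # interleaved labels on the same masses, by hand: every point scores -0.5
  expect_equal(silhouette_score(pm, c(1, 2, 1, 2)), -0.5)
  expect_error(silhouette_score(pm, c(1, 1, 1, 1)), "2 clusters")

  skip_if_not_installed("cluster")
  for (s in 1:20) {
    x <- withr::with_seed(s, matrix(rnorm(40), 20, 2))
    lab <- withr::with_seed(s + 500, sample(1:3, 20, replace = TRUE))
    if (length(unique(lab)) < 2) next
    expect_equal(silhouette_score(x, lab), brute_force_silhouette(x, lab),
                 tolerance = 1e-9)
    if (min(table(lab)) > 1) {
      ref <- mean(cluster::silhouette(lab, stats::dist(x))[, "sil_width"])
      expect_equal(silhouette_score(x, lab), ref, tolerance = 1e-9)
    }
  }
})

test_that("Davies-Bouldin matches hand values and brute force", {
  expect_equal(davies_bouldin(matrix(c(0, 0, 10, 10), 4, 1), c(1, 1, 2, 2)), 0)
  # clusters {0,2} and {10,12}: scatter 1 each, centroid distance 10
  expect_equal(davies_bouldin(matrix(c(0, 2, 10, 12), 4, 1), c(1, 1, 2, 2)),
               0.2)
  for (s in 1:20) {
    x <- withr::with_seed(s, matrix(rnorm(50), 25, 2))
    lab <- withr::with_seed(s + 700, sample(1:4, 25, replace = TRUE))
    if (length(unique(lab)) < 2) next
    expect_equal(davies_bouldin(x, lab), brute_force_davies_bouldin(x, lab),
                 tolerance = 1e-9)
  }
})

test_that("held-out assignment is nearest-centroid with a lowest-index tie-break", {
  x <- rbind(c(0, 0), c(0.1, 0), c(10, 0), c(10.1, 0), c(0, 5), c(10, 5))
  cl <- cluster_weighted(x, k = 2, seed = 1, l2_normalize = FALSE,
                         target_dim = 1)
  cent_raw <- project_features(cl$reducer, x)
  # a point identical to a training point lands in that point's cluster
  expect_equal(assign_unseen(cl, x[1, , drop = FALSE]), cl$labels[1])
  # equidistant point: lowest-index centroid wins
  mid <- matrix(colMeans(cl$centroids), 1)
  expect_equal(assign_unseen(cl, mid, reduce = FALSE), 1L)
  expect_error(assign_unseen(cl, matrix(0, 1, 5)), "dimension")
})

test_that("tidy and glance summarize a clustering fit", {
  x <- rbind(withr::with_seed(40, matrix(rnorm(40, 0, 0.1), 20, 2)),
             withr::with_seed(41, matrix(rnorm(40, 3, 0.1), 20, 2)))
  truth <- rep(c("a", "b"), each = 20)
  cl <- cluster_weighted(x, k_range = 2:4, truth = truth, seed = 9,
                         l2_normalize = FALSE)
  td <- tidy(cl)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 40)
  expect_true(all(c("id", "cluster", "truth") %in% names(td)))
  gl <- glance(cl)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$k, cl$k)
  expect_equal(gl$rand, 1.0)
})

test_that("fine-tuned features cluster at least as well as untrained features", {
  run <- benchmark_run("two_shapes")
  fit <- run$stage3$fit
  generic <- untrained_classifier(64, seed = 1)
  f_generic <- extract_features(generic, fit$weighted)
  cl_ft <- cluster_weighted(fit$features, k = 2, truth = fit$subtype, seed = 5)
  cl_gen <- cluster_weighted(f_generic, k = 2, truth = fit$subtype, seed = 5)
  expect_gte(cl_ft$rand, cl_gen$rand)
})
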