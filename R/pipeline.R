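#' Configuration for the end-to-end discovery pipeline
#'
#' Bundles the options of the four pipeline stages — synthetic data
#' generation, classifier training, occlusion explanation, and
#' explanation-weighted clustering — into one validated list. Defaults give a
#' desk-scale run: 64 px images, a patch of a quarter of the image side with
#' a stride of half the patch, smoothing at `theta = 0.1`, `sigma = 8`, and
#' silhouette-selected K over 2..6.
#'
#' @param n_total Number of generated images.
#' @param side Image side in pixels.
#' @param shapes Overlay subtypes of the pathological class
#'   (see [shape_palette()]).
#' @param pathology_rate,pip_rate,size_fraction_range,splits,stratified,background_dir
#'   Passed to [build_dataset()].
#' @param train Named list overriding [train_config()] fields. The pipeline
#'   default raises the learning rate to 0.01 and lowers the batch size to 16:
#'   [train_config()]'s own defaults describe a fine-tuning protocol for
#'   datasets of tens of thousands of images, while the desk-scale pipeline
#'   trains from scratch on a few hundred, so it needs smaller and more
#'   numerous update steps per epoch to converge at all.
#' @param channels Conv-block widths of the classifier.
#' @param augment_training Refresh random flips/rotations every epoch.
#' @param patch,stride Occlusion patch side and stride (`NULL` = side/4 and
#'   patch/2).
#' @param theta,sigma Smoothing offset and strength.
#' @param occlusion_value Gray value used for occlusion.
#' @param k Fixed cluster count (`NULL` = select by silhouette).
#' @param k_range Candidate K scanned when `k` is `NULL`.
#' @param svd_variance,max_dim Feature-reduction settings.
#' @param n_restarts K-means restarts.
#' @param seed Master seed; every stage derives its own seed from it.
#' @return A list of class `xw_pipeline_config`.
#' @export
pipeline_config <- function(n_total = 500L, side = 64L,
                            shapes = c("yellow_rect", "blue_ellipse"),
                            pathology_rate = 0.5, pip_rate = 0.3,
                            size_fraction_range = c(0.20, 0.25),
                            splits = c(train = 0.64, val = 0.16, test = 0.20),
                            stratified = FALSE, background_dir = NULL,
                            train = list(lr = 0.01, batch_size = 16L,
                                         max_epochs = 15L),
                            channels = c(16L, 32L, 64L),
                            augment_training = TRUE,
                            patch = NULL, stride = NULL,
                            theta = 0.1, sigma = 8,
                            occlusion_value = 128 / 255,
                            k = NULL, k_range = 2:6,
                            svd_variance = 0.9, max_dim = 32L,
                            n_restarts = 10L, seed = 1L) {
  if (is.null(patch)) patch <- max(2L, round(side / 4))
  if (is.null(stride)) stride <- max(1L, round(patch / 2))
  if (is.null(k)) {
    if (length(k_range) == 0 || any(diff(k_range) < 0)) {
      stop("k_range must be a non-empty ascending range (k_max >= k_min)",
           call. = FALSE)
    }
  }
  if (patch > side) stop("patch cannot exceed the image side", call. = FALSE)
  if (theta <= 0 || theta >= 1 || sigma < 1) {
    stop("need 0 < theta < 1 and sigma >= 1", call. = FALSE)
  }
  cfg <- list(
    n_total = as.integer(n_total), side = as.integer(side), shapes = shapes,
    pathology_rate = pathology_rate, pip_rate = pip_rate,
    size_fraction_range = size_fraction_range, splits = splits,
    stratified = stratified, background_dir = background_dir,
    train = train, channels = as.integer(channels),
    augment_training = augment_training,
    patch = as.integer(patch), stride = as.integer(stride),
    theta = theta, sigma = sigma, occlusion_value = occlusion_value,
    k = k, k_range = as.integer(k_range), svd_variance = svd_variance,
    max_dim = as.integer(max_dim), n_restarts = as.integer(n_restarts),
    seed = as.integer(seed)
  )
  structure(cfg, class = "xw_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @return An `xw_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$splits)) vals$splits <- unlist(vals$splits)
  if (!is.null(vals$k_range)) vals$k_range <- do.call(seq, as.list(range(unlist(vals$k_range))))
  do.call(pipeline_config, vals)
}

stage_msg <- function(stage, t0) {
  message(sprintf("[xwclust] %-8s done in %.1fs", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the four-step discovery pipeline
#'
#' Executes, in order: (1) synthetic dataset generation with ground-truth
#' masks; (2) training of the binary healthy/pathological classifier; (3)
#' occlusion explanations and explanation-weighted images for every val/test
#' image the classifier flags as pathological (probability >= 0.5), with
#' penultimate features extracted from the weighted images; (4) SVD
#' reduction and silhouette-guided K-means on the val-split features, with
#' the test-split features held out and assigned to the nearest centroid.
#' The held-out Rand index against the true overlay subtype is the headline
#' score. All outputs (dataset, model, explanations, features, cluster
#' labels, overlay gallery, JSON/Markdown summary) land under `out_dir`, and
#' the whole run is a deterministic function of the configuration.
#'
#' @param config An [pipeline_config()].
#' @param out_dir Output directory for the run.
#' @return Invisibly, a list with `summary` (also written as
#'   `summary.json`), the fitted `model`, the `clusters` object and the
#'   dataset `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "xw_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(config, file.path(out_dir, "config.rds"))
  yaml::write_yaml(unclass(config)[!vapply(unclass(config), is.null, logical(1))],
                   file.path(out_dir, "config.yaml"))

  # Stage 1: data
  t0 <- as.numeric(Sys.time())
  manifest <- build_dataset(
    file.path(out_dir, "dataset"), n_total = config$n_total,
    side = config$side, pathology_rate = config$pathology_rate,
    shapes = config$shapes, size_fraction_range = config$size_fraction_range,
    splits = config$splits, seed = config$seed, pip_rate = config$pip_rate,
    stratified = config$stratified, background_dir = config$background_dir
  )
  stage_msg("gen", t0)

  # Stage 2: classifier
  t0 <- as.numeric(Sys.time())
  tc <- do.call(train_config, c(config$train, list(seed = config$seed + 1L)))
  model <- train_classifier(manifest, arch = "small_cnn", config = tc,
                            channels = config$channels,
                            augment_training = config$augment_training)
  saveRDS(model, file.path(out_dir, "model.rds"))
  stage_msg("train", t0)

  # Stage 3: explanations, weighting, features
  t0 <- as.numeric(Sys.time())
  grid <- make_patch_grid(config$side, config$side, config$patch,
                          config$patch, config$stride)
  explain_split <- function(split) {
    dat <- load_images(manifest, split)
    prob <- predict_proba(model, dat$x)
    sel <- which(prob >= 0.5)
    if (length(sel) == 0) return(NULL)
    weighted <- array(0, c(config$side, config$side, 3, length(sel)))
    expl <- vector("list", length(sel))
    for (j in seq_along(sel)) {
      i <- sel[j]
      expl[[j]] <- explain(model, dat$x[, , , i], grid,
                           C = config$occlusion_value,
                           theta = config$theta, sigma = config$sigma)
      weighted[, , , j] <- weight_image(dat$x[, , , i], expl[[j]])
    }
    list(id = dat$id[sel], subtype = dat$subtype[sel],
         label = dat$manifest$label[sel], prob = prob[sel],
         x = dat$x[, , , sel, drop = FALSE], weighted = weighted,
         explanations = expl,
         features = extract_features(model, weighted))
  }
  stage3 <- list(fit = explain_split("val"), holdout = explain_split("test"))
  if (is.null(stage3$fit) || nrow(stage3$fit$features) < 3) {
    stop("pipeline stage 3: too few val images classified pathological",
         call. = FALSE)
  }
  saveRDS(stage3, file.path(out_dir, "stage3.rds"))
  stage_msg("explain", t0)

  # Stage 4: clustering + held-out assignment
  t0 <- as.numeric(Sys.time())
  result <- cluster_stage(stage3, config)
  saveRDS(result$clusters, file.path(out_dir, "clusters.rds"))
  readr::write_csv(result$assignments, file.path(out_dir, "cluster_labels.csv"))
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  writeLines(summary_markdown(result$summary), file.path(out_dir, "summary.md"))
  gallery <- overlay_gallery(stage3$fit)
  if (!is.null(gallery)) write_image_png(gallery, file.path(out_dir, "gallery.png"))
  stage_msg("cluster", t0)

  invisible(list(summary = result$summary, model = model,
                 clusters = result$clusters, manifest = manifest,
                 stage3 = stage3, assignments = result$assignments))
}

# Stage 4 in isolation so persisted stage-3 outputs can be re-clustered.
cluster_stage <- function(stage3, config) {
  fit <- stage3$fit
  clusters <- cluster_weighted(
    fit$features, k = config$k, k_range = config$k_range,
    truth = fit$subtype, seed = config$seed + 2L,
    n_restarts = config$n_restarts, variance = config$svd_variance,
    max_dim = config$max_dim, ids = fit$id
  )
  assignments <- tidy(clusters)
  assignments$split <- "val"
  rand_heldout <- NA_real_
  if (!is.null(stage3$holdout) && length(stage3$holdout$id) >= 2) {
    ho_labels <- assign_unseen(clusters, stage3$holdout$features)
    rand_heldout <- rand_index(stage3$holdout$subtype, ho_labels)
    assignments <- dplyr::bind_rows(
      assignments,
      tibble::tibble(id = stage3$holdout$id, cluster = factor(ho_labels),
                     truth = stage3$holdout$subtype, split = "test")
    )
  }
  summary <- list(
    k = clusters$k,
    n_fit = length(fit$id),
    n_holdout = length(stage3$holdout$id %||% character(0)),
    silhouette = clusters$silhouette,
    davies_bouldin = clusters$davies_bouldin,
    rand_insample = clusters$rand,
    rand_heldout = rand_heldout,
    cluster_sizes = as.integer(clusters$sizes),
    reduced_dim = clusters$reducer$k,
    var_explained = clusters$reducer$var_explained,
    seed = config$seed
  )
  list(clusters = clusters, assignments = assignments, summary = summary)
}

#' Re-run only the clustering stage of a persisted pipeline run
#'
#' Loads the stage-3 outputs (weighted-image features) and the configuration
#' saved by [run_pipeline()] and repeats stage 4; with the same
#' configuration this reproduces the persisted cluster result exactly.
#'
#' @param out_dir Directory of a completed [run_pipeline()] run.
#' @return As the stage-4 portion of [run_pipeline()]: list with `clusters`,
#'   `assignments`, `summary`.
#' @export
rerun_cluster <- function(out_dir) {
  stage3 <- readRDS(file.path(out_dir, "stage3.rds"))
  config <- readRDS(file.path(out_dir, "config.rds"))
  cluster_stage(stage3, config)
}

summary_markdown <- function(s) {
  c("# Explanation-weighted clustering run",
    "",
    sprintf("- images clustered (val, classified pathological): %d", s$n_fit),
    sprintf("- held-out images assigned (test): %d", s$n_holdout),
    sprintf("- selected K: %d", s$k),
    sprintf("- cluster sizes: %s", paste(s$cluster_sizes, collapse = ", ")),
    sprintf("- silhouette: %.4f", s$silhouette),
    sprintf("- Davies-Bouldin: %.4f", s$davies_bouldin),
    sprintf("- Rand (in-sample vs subtype): %.4f", s$rand_insample),
    sprintf("- Rand (held-out assignment vs subtype): %.4f", s$rand_heldout),
    sprintf("- reduced dimension: %d (%.1f%% variance)", s$reduced_dim,
            100 * s$var_explained))
}

overlay_gallery <- function(fit, n_max = 8L) {
  if (is.null(fit)) return(NULL)
  n <- min(n_max, length(fit$id))
  tiles <- lapply(seq_len(n), function(j) {
    cbind_images(render_overlay(fit$x[, , , j], fit$explanations[[j]]),
                 fit$weighted[, , , j])
  })
  tile_images(tiles, ncol = 2L)
}

cbind_images <- function(a, b, pad = 2L) {
  out <- array(0, c(dim(a)[1], dim(a)[2] + pad + dim(b)[2], 3))
  out[, seq_len(dim(a)[2]), ] <- a
  out[, dim(a)[2] + pad + seq_len(dim(b)[2]), ] <- b
  out
}

#' Desk-scale benchmark configurations
#'
#' Canonical configurations for the two bundled end-to-end benchmarks:
#' `two_shapes` pairs a yellow rectangle with a blue ellipse (the easy
#' subtype pair), `polyp_analog` pairs an irregular pink blob — a polyp
#' stand-in — with a blue ellipse of comparable size (the hard pair). Both
#' use 500 images at 64 px, occlusion patch 16 with stride 8, smoothing
#' `theta = 0.1`, `sigma = 8`, and silhouette-selected K over 2..6.
#'
#' @param variant Which subtype pair to generate.
#' @param seed Master seed of the run.
#' @param ... Further overrides passed to [pipeline_config()].
#' @return An `xw_pipeline_config`.
#' @export
benchmark_config <- function(variant = c("two_shapes", "polyp_analog"),
                             seed = 42L, ...) {
  variant <- match.arg(variant)
  shapes <- switch(variant,
    two_shapes = c("yellow_rect", "blue_ellipse"),
    polyp_analog = c("pink_blob", "blue_ellipse")
  )
  pipeline_config(n_total = 500L, side = 64L, patch = 16L, stride = 8L,
                  shapes = shapes, seed = as.integer(seed), ...)
}
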