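#' Training configuration
#'
#' Defaults follow the study protocol for the binary classifier: batch size
#' 64, binary cross-entropy, SGD with learning rate 0.001 and momentum 0.9,
#' learning rate multiplied by 0.1 every 7 epochs, early stopping when the
#' validation F1 score fails to improve for 5 consecutive epochs.
#'
#' @param batch_size Mini-batch size.
#' @param lr Initial learning rate (> 0).
#' @param momentum SGD momentum.
#' @param lr_decay_factor Multiplicative decay in `(0, 1]`.
#' @param lr_decay_period Epochs between decays.
#' @param patience Early-stopping patience in epochs (>= 1).
#' @param max_epochs Hard epoch cap.
#' @param seed Integer seed covering initialization, shuffling and
#'   augmentation.
#' @return A list of class `xw_train_config`.
#' @export
train_config <- function(batch_size = 64L, lr = 1e-3, momentum = 0.9,
                         lr_decay_factor = 0.1, lr_decay_period = 7L,
                         patience = 5L, max_epochs = 20L, seed = 1L) {
  stopifnot(lr > 0, patience >= 1, lr_decay_factor > 0, lr_decay_factor <= 1,
            batch_size >= 1, max_epochs >= 1)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum, lr_decay_factor = lr_decay_factor,
                 lr_decay_period = as.integer(lr_decay_period),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "xw_train_config")
}

#' Learning rate under stepped decay
#'
#' @param epoch 1-based epoch number.
#' @param lr Initial learning rate.
#' @param factor,period Decay factor and period (epochs).
#' @return The learning rate in effect at `epoch`.
#' @export
lr_at_epoch <- function(epoch, lr = 1e-3, factor = 0.1, period = 7L) {
  lr * factor^((epoch - 1) %/% period)
}

#' F1 score of binary predictions
#'
#' @param truth,pred 0/1 vectors.
#' @return `2TP / (2TP + FP + FN)`; 0 when that denominator is 0.
#' @export
f1_score <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Early-stopping epoch for a metric trajectory
#'
#' Given per-epoch values of a higher-is-better validation metric, returns the
#' epoch at which training halts: the first epoch lying `patience` epochs past
#' the best-so-far (strict improvements only), or the last epoch if that never
#' happens.
#'
#' @param metrics Numeric vector of per-epoch validation scores.
#' @param patience Number of non-improving epochs tolerated.
#' @return Integer epoch index at which training stops.
#' @export
early_stop_epoch <- function(metrics, patience) {
  best <- -Inf
  best_epoch <- 0L
  for (e in seq_along(metrics)) {
    if (metrics[e] > best) {
      best <- metrics[e]
      best_epoch <- e
    } else if (e - best_epoch >= patience) {
      return(e)
    }
  }
  length(metrics)
}

new_small_cnn <- function(side, channels = c(16L, 32L, 64L)) {
  L <- length(channels)
  if (side %% (2^L) != 0 || side < 2^L) {
    stop("input side must be divisible by 2^", L, call. = FALSE)
  }
  cin <- c(3L, channels[-L])
  conv_w <- conv_b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- cin[l] * 9
    conv_w[[l]] <- matrix(rnorm(channels[l] * fan_in) * sqrt(2 / fan_in),
                          channels[l], fan_in)
    conv_b[[l]] <- rep(0, channels[l])
  }
  fdim <- channels[L]
  list(conv_w = conv_w, conv_b = conv_b,
       dense_w = rnorm(fdim) * sqrt(1 / fdim), dense_b = 0)
}

as_image_batch <- function(images, side = NULL) {
  if (length(dim(images)) == 3L) images <- array(images, c(dim(images), 1L))
  stopifnot(length(dim(images)) == 4L, dim(images)[3] == 3L)
  if (!is.null(side) && (dim(images)[1] != side || dim(images)[2] != side)) {
    stop("image side ", dim(images)[1], "x", dim(images)[2],
         " does not match the classifier input side ", side, call. = FALSE)
  }
  images
}

# Inputs are centered and scaled to [-1, 1] inside the model so that the
# first conv layer sees zero-mean activations; the user-facing contract
# remains images in [0, 1].
cnn_scale_input <- function(images) (images - 0.5) * 2

cnn_eval <- function(params, images, want_features = FALSE) {
  images <- cnn_scale_input(images)
  d <- dim(images)
  cnn_forward_cpp(params$conv_w, params$conv_b, params$dense_w, params$dense_b,
                  as.numeric(images), d[1], d[2], d[3], d[4], want_features)
}

#' Train the desk-scale convolutional classifier
#'
#' Fits a small convolutional network (3x3 conv / ReLU / 2x2 max-pool blocks,
#' global average pooling into the penultimate feature vector, a single
#' sigmoid logit) to separate healthy from pathological images, using SGD with
#' momentum on binary cross-entropy, stepped learning-rate decay, and early
#' stopping on the validation F1 score. The weights achieving the best
#' validation F1 are restored at the end. The framework treats this model as a
#' black box: any predictor exposing a probability and a penultimate feature
#' vector can stand in for it downstream.
#'
#' @param data A dataset manifest (from [build_dataset()] / [read_manifest()])
#'   with non-empty `train` and `val` splits, or a list with elements
#'   `x_train`, `y_train`, `x_val`, `y_val` (arrays `S x S x 3 x n`, 0/1
#'   labels).
#' @param arch Architecture name; `"small_cnn"` is the implemented desk-scale
#'   model.
#' @param config An [train_config()].
#' @param channels Output channels of the successive conv blocks; the last
#'   entry is the penultimate feature dimension.
#' @param augment_training Apply random flip/rotate augmentation to each
#'   training image, refreshed every epoch.
#' @return A classifier handle of class `xw_classifier` with the fitted
#'   parameters, training `history` (tibble: epoch, lr, train loss, val F1)
#'   and `val_f1`, the best validation F1.
#' @export
train_classifier <- function(data, arch = "small_cnn", config = train_config(),
                             channels = c(16L, 32L, 64L),
                             augment_training = TRUE) {
  if (!identical(arch, "small_cnn")) {
    stop("only the 'small_cnn' architecture is available in this build; ",
         "a transfer-learned deep residual network would require pretrained ",
         "weights and a GPU-scale framework", call. = FALSE)
  }
  if (is.data.frame(data)) {
    tr <- load_images(data, "train")
    va <- load_images(data, "val")
    data <- list(x_train = tr$x, y_train = tr$y, x_val = va$x, y_val = va$y)
  }
  x_train <- as_image_batch(data$x_train)
  x_val <- as_image_batch(data$x_val)
  y_train <- as.numeric(data$y_train)
  y_val <- as.numeric(data$y_val)
  if (length(unique(y_train)) < 2) {
    stop("training split must contain both classes", call. = FALSE)
  }
  side <- dim(x_train)[1]
  stopifnot(dim(x_train)[2] == side)

  withr::with_seed(config$seed, {
    params <- new_small_cnn(side, channels)
    vel <- lapply(params, function(p) {
      if (is.list(p)) lapply(p, function(q) q * 0) else p * 0
    })
    n <- dim(x_train)[4]
    history <- vector("list", config$max_epochs)
    best_f1 <- -Inf
    best_epoch <- 0L
    f1s <- numeric(0)
    f1 <- NA_real_

    for (epoch in seq_len(config$max_epochs)) {
      lr <- lr_at_epoch(epoch, config$lr, config$lr_decay_factor,
                        config$lr_decay_period)
      ord <- sample.int(n)
      xe <- x_train
      if (augment_training) {
        for (i in seq_len(n)) xe[, , , i] <- augment(x_train[, , , i])
      }
      losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        xb <- cnn_scale_input(xe[, , , idx, drop = FALSE])
        d <- dim(xb)
        g <- cnn_grad_cpp(params$conv_w, params$conv_b, params$dense_w,
                          params$dense_b, as.numeric(xb),
                          d[1], d[2], d[3], d[4], y_train[idx])
        losses <- c(losses, g$loss)
        for (l in seq_along(params$conv_w)) {
          vel$conv_w[[l]] <- config$momentum * vel$conv_w[[l]] - lr * g$conv_w[[l]]
          params$conv_w[[l]] <- params$conv_w[[l]] + vel$conv_w[[l]]
          vel$conv_b[[l]] <- config$momentum * vel$conv_b[[l]] - lr * g$conv_b[[l]]
          params$conv_b[[l]] <- params$conv_b[[l]] + vel$conv_b[[l]]
        }
        vel$dense_w <- config$momentum * vel$dense_w - lr * g$dense_w
        params$dense_w <- params$dense_w + vel$dense_w
        vel$dense_b <- config$momentum * vel$dense_b - lr * g$dense_b
        params$dense_b <- params$dense_b + vel$dense_b
      }
      val_prob <- cnn_eval(params, x_val)$prob
      f1 <- f1_score(y_val, as.integer(val_prob >= 0.5))
      f1s <- c(f1s, f1)
      history[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                         train_loss = mean(losses), val_f1 = f1)
      if (f1 > best_f1) {
        best_f1 <- f1
        best_epoch <- epoch
      }
      if (epoch - best_epoch >= config$patience) break
    }

    # Early stopping halts training; the parameters at the stopping epoch are
    # kept (training past the first F1 plateau keeps sharpening the margin).
    structure(
      list(params = params, arch = arch, side = side,
           channels = as.integer(channels),
           feature_dim = as.integer(channels[length(channels)]),
           history = dplyr::bind_rows(history), val_f1 = f1,
           best_val_f1 = best_f1, config = config),
      class = "xw_classifier"
    )
  })
}

#' Untrained classifier of the same architecture
#'
#' A randomly initialized handle, useful as the "generic features" baseline
#' against which fine-tuned features are compared.
#'
#' @inheritParams train_classifier
#' @param side Input side length.
#' @param seed Integer seed for the random initialization.
#' @return An `xw_classifier` handle (untrained).
#' @export
untrained_classifier <- function(side, channels = c(16L, 32L, 64L), seed = 1L) {
  params <- withr::with_seed(as.integer(seed), new_small_cnn(side, channels))
  structure(
    list(params = params, arch = "small_cnn", side = as.integer(side),
         channels = as.integer(channels),
         feature_dim = as.integer(channels[length(channels)]),
         history = tibble::tibble(), val_f1 = NA_real_,
         config = NULL),
    class = "xw_classifier"
  )
}

#' Predicted probability of the pathological class
#'
#' @param handle An `xw_classifier`.
#' @param images One image (`S x S x 3`) or a batch (`S x S x 3 x n`).
#' @return Numeric vector of probabilities in `[0, 1]`; the classification
#'   rule is pathological iff the probability is at least 0.5.
#' @export
predict_proba <- function(handle, images) {
  stopifnot(inherits(handle, "xw_classifier"))
  x <- as_image_batch(images, handle$side)
  cnn_eval(handle$params, x)$prob
}

#' Penultimate-layer features
#'
#' The global-average-pooled activations feeding the final decision neuron,
#' used as the learned embedding of (weighted) images.
#'
#' @inheritParams predict_proba
#' @return `n x feature_dim` numeric matrix.
#' @export
extract_features <- function(handle, images) {
  stopifnot(inherits(handle, "xw_classifier"))
  x <- as_image_batch(images, handle$side)
  cnn_eval(handle$params, x, want_features = TRUE)$features
}

#' @export
print.xw_classifier <- function(x, ...) {
  cat("<xw_classifier> ", x$arch, ", input ", x$side, "x", x$side,
      ", features ", x$feature_dim, "-d", sep = "")
  if (!is.na(x$val_f1)) cat(", best val F1 ", signif(x$val_f1, 4), sep = "")
  cat("\n")
  invisible(x)
}

# Uniform functional view of a classifier: batch array -> probability vector.
# Plain R functions (taking a single image) are accepted so toy classifiers
# can drive the attribution machinery.
classifier_fun <- function(handle) {
  if (inherits(handle, "xw_classifier")) {
    function(batch) cnn_eval(handle$params, as_image_batch(batch, handle$side))$prob
  } else if (is.function(handle)) {
    function(batch) {
      batch <- as_image_batch(batch)
      vapply(seq_len(dim(batch)[4]),
             function(i) as.numeric(handle(batch[, , , i])), numeric(1))
    }
  } else {
    stop("classifier must be an xw_classifier or a function", call. = FALSE)
  }
}
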