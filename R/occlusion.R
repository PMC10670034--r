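#' Importance maps
#'
#' An importance map holds one attribution value per pixel of the image it
#' explains, together with a stage tag: `raw` (mean probability drops),
#' `normalized` (positive part scaled to `[0, 1]` by the maximum positive
#' value, negative part to `[-1, 0]` by the most negative value), or
#' `smoothed` (after the two-branch power transform). `f_ref` records the
#' unoccluded probability the drops are measured against.
#'
#' @param values Numeric `H x W` matrix.
#' @param stage One of `"raw"`, `"normalized"`, `"smoothed"`.
#' @param f_ref Reference probability of the unmodified image.
#' @param meta Optional list of provenance (grid, occlusion colour, theta,
#'   sigma).
#' @return An object of class `xw_importance`.
#' @export
importance_map <- function(values, stage = c("raw", "normalized", "smoothed"),
                           f_ref = NA_real_, meta = list()) {
  stage <- match.arg(stage)
  stopifnot(is.matrix(values))
  structure(list(values = values, stage = stage, f_ref = f_ref, meta = meta),
            class = "xw_importance")
}

#' @export
print.xw_importance <- function(x, ...) {
  cat("<xw_importance> ", nrow(x$values), "x", ncol(x$values),
      " (", x$stage, "), range [", signif(min(x$values), 3), ", ",
      signif(max(x$values), 3), "]\n", sep = "")
  invisible(x)
}

#' Build an occlusion patch grid
#'
#' Places `patch_h x patch_w` rectangles at top-left positions spaced by
#' `stride`, adding a final row/column of patches clamped flush to the
#' bottom/right edges whenever the regular stride grid would leave pixels
#' uncovered — so every pixel belongs to at least one patch for any
#' size/stride combination.
#'
#' @param H,W Image dimensions.
#' @param patch_h,patch_w Patch dimensions (within the image).
#' @param stride Step between successive patch positions (>= 1).
#' @return An `xw_patch_grid`: a list with the patch geometry and `rects`, a
#'   tibble of 1-based `(top, left, height, width)` rectangles.
#' @export
make_patch_grid <- function(H, W, patch_h, patch_w = patch_h, stride = 1L) {
  if (patch_h < 1 || patch_w < 1 || patch_h > H || patch_w > W) {
    stop("patch must fit inside the image", call. = FALSE)
  }
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  if (stride > min(patch_h, patch_w)) {
    stop("stride must not exceed the patch size, or pixels between ",
         "successive patches would never be covered", call. = FALSE)
  }
  axis_positions <- function(n, p) {
    pos <- seq(1L, n - p + 1L, by = stride)
    if (pos[length(pos)] != n - p + 1L) pos <- c(pos, n - p + 1L)
    pos
  }
  tops <- axis_positions(H, patch_h)
  lefts <- axis_positions(W, patch_w)
  rects <- tibble::tibble(
    top = rep(tops, times = length(lefts)),
    left = rep(lefts, each = length(tops)),
    height = patch_h, width = patch_w
  )
  structure(list(patch_h = patch_h, patch_w = patch_w, stride = stride,
                 H = H, W = W, n = nrow(rects), rects = rects),
            class = "xw_patch_grid")
}

#' @export
print.xw_patch_grid <- function(x, ...) {
  cat("<xw_patch_grid> ", x$n, " patches of ", x$patch_h, "x", x$patch_w,
      " at stride ", x$stride, " on ", x$H, "x", x$W, "\n", sep = "")
  invisible(x)
}

#' Occlude a rectangle with a neutral gray
#'
#' @param image `H x W x 3` array.
#' @param rect Numeric `(top, left, height, width)`, 1-based, inside the
#'   image, with positive area.
#' @param C Occlusion value, identical in all channels. The default is the
#'   customary mid-gray, 128 on the 8-bit scale.
#' @return A copy of `image` with the rectangle set to `C` in every channel;
#'   all other pixels are bit-identical to the input.
#' @export
occlude <- function(image, rect, C = 128 / 255) {
  image <- as_raw_image(image, min_side = 1L)
  rect <- as.integer(round(rect))
  if (length(rect) != 4 || rect[3] < 1 || rect[4] < 1) {
    stop("rect must be (top, left, height, width) with positive area",
         call. = FALSE)
  }
  H <- dim(image)[1]
  W <- dim(image)[2]
  if (rect[1] < 1 || rect[2] < 1 ||
      rect[1] + rect[3] - 1 > H || rect[2] + rect[4] - 1 > W) {
    stop("rect lies outside the image", call. = FALSE)
  }
  image[rect[1]:(rect[1] + rect[3] - 1),
        rect[2]:(rect[2] + rect[4] - 1), ] <- C
  image
}

#' Raw occlusion attribution map
#'
#' For every patch in the grid, the image is copied with the patch replaced by
#' the gray value `C` and passed through the classifier; each pixel's raw
#' importance is the mean of `f(I) - f(occluded)` over exactly the patches
#' covering it. `f(I)` is evaluated once and reused; occluded variants are
#' evaluated as one batch (results are independent of batching since the
#' classifier is applied per image).
#'
#' @param handle An `xw_classifier`, or any function mapping one image to a
#'   probability.
#' @param image `H x W x 3` array matching the classifier input size.
#' @param grid An [make_patch_grid()] over the image dimensions.
#' @param C Occlusion gray value.
#' @return An `xw_importance` at stage `"raw"`.
#' @export
attribution_map <- function(handle, image, grid, C = 128 / 255) {
  image <- as_raw_image(image, min_side = 1L)
  stopifnot(inherits(grid, "xw_patch_grid"))
  H <- dim(image)[1]
  W <- dim(image)[2]
  if (grid$H != H || grid$W != W) {
    stop("grid dimensions do not match the image", call. = FALSE)
  }
  f <- classifier_fun(handle)
  f0 <- f(image)
  n <- grid$n
  occ <- array(0, c(H, W, 3, n))
  for (i in seq_len(n)) {
    r <- grid$rects[i, ]
    occ[, , , i] <- occlude(image, c(r$top, r$left, r$height, r$width), C)
  }
  drops <- f0 - f(occ)
  acc <- matrix(0, H, W)
  cnt <- matrix(0L, H, W)
  for (i in seq_len(n)) {
    r <- grid$rects[i, ]
    rows <- r$top:(r$top + r$height - 1)
    cols <- r$left:(r$left + r$width - 1)
    acc[rows, cols] <- acc[rows, cols] + drops[i]
    cnt[rows, cols] <- cnt[rows, cols] + 1L
  }
  if (any(cnt == 0L)) stop("patch grid does not cover the image", call. = FALSE)
  importance_map(acc / cnt, "raw", f_ref = f0,
                 meta = list(patch_h = grid$patch_h, patch_w = grid$patch_w,
                             stride = grid$stride, C = C))
}

#' Signed normalization of an importance map
#'
#' Positive entries are divided by the largest positive entry, negative
#' entries by the magnitude of the most negative entry; zeros pass through.
#' The result lies in `[-1, 1]` with the extremes attained (when the
#' corresponding sign is present). Normalization is idempotent and invariant
#' to positive rescaling of the input.
#'
#' @param map An `xw_importance` (stage `raw` or `normalized`).
#' @return An `xw_importance` at stage `"normalized"`.
#' @export
normalize_importance <- function(map) {
  stopifnot(inherits(map, "xw_importance"))
  v <- map$values
  pos <- v > 0
  neg <- v < 0
  if (any(pos)) v[pos] <- v[pos] / max(v[pos])
  if (any(neg)) v[neg] <- v[neg] / abs(min(v[neg]))
  importance_map(v, "normalized", f_ref = map$f_ref, meta = map$meta)
}

#' Two-branch power smoothing transform
#'
#' `S(x, theta, sigma) = x^sigma / theta^(sigma-1)` for `x <= theta` and
#' `1 - (1-x)^sigma / (1-theta)^(sigma-1)` otherwise. On `[0, 1]` it is
#' continuous (including at `theta`), strictly increasing for `sigma >= 1`,
#' and fixes 0, `theta` and 1 — so values below the offset `theta` are
#' suppressed toward 0 and values above it amplified toward 1, sharpening the
#' explanation. `sigma` controls how hard the transition is.
#'
#' @param x Numeric vector in `[0, 1]`.
#' @param theta Offset in `(0, 1)` where suppression turns into amplification.
#' @param sigma Strength (>= 1).
#' @return `S(x, theta, sigma)`, same shape as `x`.
#' @export
smooth_value <- function(x, theta = 0.1, sigma = 8) {
  stopifnot(theta > 0, theta < 1, sigma >= 1)
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    stop("smooth_value() is defined on [0, 1]", call. = FALSE)
  }
  ifelse(x <= theta,
         x^sigma / theta^(sigma - 1),
         1 - (1 - x)^sigma / (1 - theta)^(sigma - 1))
}

#' Smooth a normalized importance map
#'
#' Applies [smooth_value()] to the magnitude of each entry and restores the
#' sign, so the green/red (positive/negative) semantics of the map are
#' preserved symmetrically; zeros stay zero.
#'
#' @param map An `xw_importance` at stage `"normalized"`.
#' @inheritParams smooth_value
#' @return An `xw_importance` at stage `"smoothed"`.
#' @export
smooth_map <- function(map, theta = 0.1, sigma = 8) {
  stopifnot(inherits(map, "xw_importance"))
  if (map$stage != "normalized") {
    stop("smooth_map() expects a normalized map", call. = FALSE)
  }
  v <- sign(map$values) * smooth_value(abs(map$values), theta, sigma)
  meta <- map$meta
  meta$theta <- theta
  meta$sigma <- sigma
  importance_map(v, "smoothed", f_ref = map$f_ref, meta = meta)
}

#' Full occlusion explanation of one image
#'
#' Composes [attribution_map()], [normalize_importance()] and [smooth_map()].
#' When `grid` is omitted, the patch side defaults to the image side divided
#' by 3.5 (rounded) and the stride to a third of the patch, mirroring the
#' patch-to-image ratios used in the reference experiments (224 -> 64 -> 16).
#'
#' @inheritParams attribution_map
#' @inheritParams smooth_value
#' @param grid Optional [make_patch_grid()].
#' @return An `xw_importance` at stage `"smoothed"`.
#' @export
explain <- function(handle, image, grid = NULL, C = 128 / 255,
                    theta = 0.1, sigma = 8) {
  image <- as_raw_image(image, min_side = 1L)
  if (is.null(grid)) {
    side <- min(dim(image)[1:2])
    patch <- max(1L, round(side / 3.5))
    grid <- make_patch_grid(dim(image)[1], dim(image)[2], patch, patch,
                            max(1L, round(patch / 3)))
  }
  smooth_map(normalize_importance(attribution_map(handle, image, grid, C)),
             theta, sigma)
}
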