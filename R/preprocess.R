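#' Bottom-left square crop and resize
#'
#' Crops an image to a 1:1 aspect ratio by keeping the full shorter dimension
#' and anchoring the crop window at the bottom-left corner (excess rows are
#' discarded from the top, excess columns from the right), then resizes
#' bilinearly to `target_side`. The bottom-left anchor keeps any
#' picture-in-picture inset — which sits in that corner in endoscopy frames —
#' inside the crop. When the cropped side already equals `target_side` the
#' result is returned without resampling, bit-identical to the crop.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param target_side Output side length (>= 1).
#' @return A `target_side x target_side x 3` array in `[0, 1]`.
#' @export
crop_and_resize <- function(image, target_side) {
  image <- as_raw_image(image, min_side = 1L)
  if (target_side < 1) stop("target_side must be >= 1", call. = FALSE)
  H <- dim(image)[1]
  W <- dim(image)[2]
  side <- min(H, W)
  cropped <- image[(H - side + 1):H, 1:side, , drop = FALSE]
  if (side == target_side) return(cropped)
  out <- from_ebimage(EBImage::resize(as_ebimage(cropped),
                                      w = target_side, h = target_side))
  clamp01(out)
}

#' Random flip-and-rotate augmentation
#'
#' Applies, in order: a horizontal flip with probability `p_flip`, a vertical
#' flip with probability `p_flip`, and a rotation by an angle drawn uniformly
#' from `[0, max_rotation]` degrees. Rotation resamples bilinearly with
#' reflect padding, so no constant-colour corners are introduced that a
#' classifier could latch onto.
#'
#' @param image Square `S x S x 3` array in `[0, 1]`.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (the draw order is fixed: horizontal flip, vertical flip, angle).
#' @param p_flip Per-axis flip probability.
#' @param max_rotation Upper bound of the rotation angle in degrees.
#' @return Augmented array of the same shape, values in `[0, 1]`.
#' @export
augment <- function(image, seed = NULL, p_flip = 0.5, max_rotation = 90) {
  image <- as_raw_image(image)
  if (dim(image)[1] != dim(image)[2]) {
    stop("augment() expects a square image", call. = FALSE)
  }
  run <- function() {
    hflip <- runif(1) < p_flip
    vflip <- runif(1) < p_flip
    angle <- runif(1, 0, max_rotation)
    out <- image
    if (hflip) out <- out[, rev(seq_len(dim(out)[2])), , drop = FALSE]
    if (vflip) out <- out[rev(seq_len(dim(out)[1])), , , drop = FALSE]
    if (angle > 1e-9) out <- rotate_reflect(out, angle)
    clamp01(out)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

# Rotate about the image centre, sampling bilinearly with reflect padding.
rotate_reflect <- function(image, angle_deg) {
  H <- dim(image)[1]
  W <- dim(image)[2]
  th <- angle_deg * pi / 180
  cy <- H / 2
  cx <- W / 2
  y <- matrix(seq_len(H) - 0.5, H, W) - cy
  x <- matrix(rep(seq_len(W) - 0.5, each = H), H, W) - cx
  # inverse rotation: source coordinates that land on each output pixel
  sx <- cos(th) * x + sin(th) * y + cx
  sy <- -sin(th) * x + cos(th) * y + cy
  reflect <- function(p, n) {
    p <- abs(p)
    p <- p %% (2 * n)
    ifelse(p > n, 2 * n - p, p)
  }
  sx <- reflect(sx, W)
  sy <- reflect(sy, H)
  ix0 <- pmin(pmax(floor(sx - 0.5) + 1, 1), W)
  iy0 <- pmin(pmax(floor(sy - 0.5) + 1, 1), H)
  ix1 <- pmin(ix0 + 1, W)
  iy1 <- pmin(iy0 + 1, H)
  wx <- pmin(pmax(sx - 0.5 - (ix0 - 1), 0), 1)
  wy <- pmin(pmax(sy - 0.5 - (iy0 - 1), 0), 1)
  out <- array(0, dim(image))
  for (ch in 1:3) {
    pl <- image[, , ch]
    out[, , ch] <-
      pl[cbind(c(iy0), c(ix0))] * (1 - c(wy)) * (1 - c(wx)) +
      pl[cbind(c(iy1), c(ix0))] * c(wy) * (1 - c(wx)) +
      pl[cbind(c(iy0), c(ix1))] * (1 - c(wy)) * c(wx) +
      pl[cbind(c(iy1), c(ix1))] * c(wy) * c(wx)
  }
  out
}
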