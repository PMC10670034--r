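#' Shape specifications for synthetic pathology overlays
#'
#' A shape spec describes one coloured overlay: an axis-aligned (optionally
#' rotated) rectangle, an ellipse, or an irregular "blob" (an ellipse whose
#' boundary radius is perturbed by a low-order random harmonic series, standing
#' in for polyp-like protrusions). Sizes and positions are expressed as
#' fractions of the image dimensions so a spec is resolution independent.
#'
#' @param kind One of `"rectangle"`, `"ellipse"`, `"blob"`.
#' @param color RGB triple in `[0, 1]`.
#' @param size_fraction Length-2 numeric `(width, height)` as fractions of the
#'   image width/height, each in `(0, 1)`.
#' @param position Length-2 numeric `(row, col)` fractional coordinates of the
#'   shape centre.
#' @param rotation Rotation of the shape in degrees (counter-clockwise).
#' @param blob_coef Optional numeric vector of boundary-harmonic amplitudes for
#'   `kind = "blob"`; drawn from the current RNG stream when missing.
#' @return An object of class `xw_shape_spec`.
#' @export
shape_spec <- function(kind = c("rectangle", "ellipse", "blob"),
                       color,
                       size_fraction,
                       position = c(0.5, 0.5),
                       rotation = 0,
                       blob_coef = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(color) == 3, all(color >= 0), all(color <= 1),
            length(size_fraction) == 2, all(size_fraction > 0),
            all(size_fraction < 1), length(position) == 2)
  structure(
    list(kind = kind, color = color, size_fraction = size_fraction,
         position = position, rotation = rotation, blob_coef = blob_coef),
    class = "xw_shape_spec"
  )
}

#' Built-in overlay palette
#'
#' Named overlay families used by [build_dataset()]: a yellow rectangle and a
#' blue ellipse (the two easy pathology subtypes), plus a pink irregular blob
#' as a polyp stand-in for the harder pairing. Colours are exact multiples of
#' 1/255 so 8-bit PNG round-trips preserve them bit-exactly.
#'
#' @return Named list mapping palette names to `kind` and `color`.
#' @export
shape_palette <- function() {
  list(
    yellow_rect = list(kind = "rectangle", color = c(242, 217, 26) / 255),
    blue_ellipse = list(kind = "ellipse", color = c(38, 64, 217) / 255),
    pink_blob = list(kind = "blob", color = c(250, 148, 168) / 255)
  )
}

# Number of boundary harmonics and their relative amplitude for blobs.
BLOB_HARMONICS <- 2:5
BLOB_AMPLITUDE <- 0.18

draw_blob_coef <- function() {
  stats::runif(2 * length(BLOB_HARMONICS), -BLOB_AMPLITUDE, BLOB_AMPLITUDE)
}

# Half-extents (in pixels, x then y) of the axis-aligned bounding box of a
# spec placed on an H x W image; used for placement validation and sampling.
shape_extent <- function(spec, H, W) {
  w <- spec$size_fraction[1] * W
  h <- spec$size_fraction[2] * H
  th <- spec$rotation * pi / 180
  if (spec$kind == "blob") {
    amp <- if (is.null(spec$blob_coef)) {
      2 * length(BLOB_HARMONICS) * BLOB_AMPLITUDE
    } else {
      sum(abs(spec$blob_coef))
    }
    r <- max(w, h) / 2 * (1 + amp)
    return(c(r, r))
  }
  c(abs(cos(th)) * w / 2 + abs(sin(th)) * h / 2,
    abs(sin(th)) * w / 2 + abs(cos(th)) * h / 2)
}

#' Overlay a coloured shape on an image
#'
#' Pixels whose centres fall inside the shape are replaced by the spec colour;
#' all other pixels are untouched. The returned mask marks exactly the replaced
#' pixels, providing the ground-truth explanation for the overlay.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param spec An [shape_spec()].
#' @param seed Optional integer seed for the blob boundary randomness; when
#'   `NULL` the current RNG stream is used.
#' @return A list with elements `image` (the overlaid copy) and `mask`
#'   (logical `H x W` matrix).
#' @export
overlay_shape <- function(image, spec, seed = NULL) {
  image <- as_raw_image(image)
  stopifnot(inherits(spec, "xw_shape_spec"))
  H <- dim(image)[1]
  W <- dim(image)[2]
  run <- function() {
    if (spec$kind == "blob" && is.null(spec$blob_coef)) {
      spec$blob_coef <- draw_blob_coef()
    }
    ext <- shape_extent(spec, H, W)
    cy <- spec$position[1] * H
    cx <- spec$position[2] * W
    if (cx - ext[1] < -1e-9 || cx + ext[1] > W + 1e-9 ||
        cy - ext[2] < -1e-9 || cy + ext[2] > H + 1e-9) {
      stop("shape placement exceeds image bounds", call. = FALSE)
    }
    mask <- rasterize_shape(spec, H, W)
    out <- image
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[mask] <- spec$color[ch]
      out[, , ch] <- plane
    }
    list(image = out, mask = mask)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

rasterize_shape <- function(spec, H, W) {
  cy <- spec$position[1] * H
  cx <- spec$position[2] * W
  w <- spec$size_fraction[1] * W
  h <- spec$size_fraction[2] * H
  # pixel-centre coordinates, origin at the top-left image corner
  y <- matrix(seq_len(H) - 0.5, H, W) - cy
  x <- matrix(rep(seq_len(W) - 0.5, each = H), H, W) - cx
  th <- spec$rotation * pi / 180
  if (th != 0) {
    u <- cos(th) * x + sin(th) * y
    v <- -sin(th) * x + cos(th) * y
    x <- u
    y <- v
  }
  switch(spec$kind,
    rectangle = (x >= -w / 2 & x < w / 2 & y >= -h / 2 & y < h / 2),
    ellipse = ((x / (w / 2))^2 + (y / (h / 2))^2 <= 1),
    blob = {
      a <- w / 2
      b <- h / 2
      phi <- atan2(y, x)
      r_ell <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
      co <- spec$blob_coef
      k <- BLOB_HARMONICS
      rho <- 1 + Reduce(`+`, lapply(seq_along(k), function(i) {
        co[i] * cos(k[i] * phi) + co[length(k) + i] * sin(k[i] * phi)
      }))
      sqrt(x^2 + y^2) <= r_ell * rho
    }
  )
}
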