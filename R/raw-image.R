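#' Raw images
#'
#' Throughout the package an image is a plain numeric array of shape
#' `H x W x 3` (rows, columns, RGB channels) with intensities in `[0, 1]`.
#' These helpers validate, clamp, read and write that representation.
#'
#' @param x An object to validate or coerce.
#' @param min_side Smallest admissible height/width.
#' @return `as_raw_image()` returns the validated array.
#' @name raw_image
NULL

#' @rdname raw_image
#' @export
as_raw_image <- function(x, min_side = 8L) {
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L) {
    stop("an image must be an H x W x 3 numeric array", call. = FALSE)
  }
  if (dim(x)[1] < min_side || dim(x)[2] < min_side) {
    stop("image dimensions must be at least ", min_side, " x ", min_side,
         call. = FALSE)
  }
  if (anyNA(x) || min(x) < 0 || max(x) > 1) {
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  }
  x
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Quantize intensities to the 8-bit grid
#'
#' PNG files store 8-bit samples; applying the same rounding in memory keeps
#' in-memory images byte-identical to their files.
#'
#' @param x Numeric array in `[0, 1]`.
#' @return Array with every value an exact multiple of `1/255`.
#' @export
quantize8 <- function(x) round(x * 255) / 255

#' Read / write images and masks as PNG
#'
#' Images are 8-bit RGB PNGs; masks are single-channel PNGs holding 0 or 255.
#'
#' @param path File path.
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param mask Logical or 0/1 matrix.
#' @name image_io
NULL

#' @rdname image_io
#' @export
write_image_png <- function(image, path) {
  png::writePNG(clamp01(image), target = path)
  invisible(path)
}

#' @rdname image_io
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  x
}

#' @rdname image_io
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), target = path)
  invisible(path)
}

#' @rdname image_io
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x >= 0.5
}

# EBImage stores pixels as (x, y, channel); our arrays are (row, col, channel).
as_ebimage <- function(image) {
  EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
}

from_ebimage <- function(img) {
  aperm(EBImage::imageData(img), c(2, 1, 3))
}
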