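#' Explanation-weighted image
#'
#' The Hadamard product of an image with the non-negative part of its
#' explanation: negative importances are set to zero and the resulting
#' `H x W` weight matrix multiplies every channel. Pixels deemed irrelevant
#' (or counter-indicative) go to black, isolating the characteristics that
#' drove the pathological classification.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param explanation An `xw_importance` (any stage) or numeric `H x W`
#'   matrix with values in `[-1, 1]`.
#' @return `H x W x 3` array: `I * max(Y, 0)` elementwise.
#' @export
weight_image <- function(image, explanation) {
  image <- as_raw_image(image, min_side = 1L)
  v <- if (inherits(explanation, "xw_importance")) explanation$values
       else explanation
  stopifnot(is.matrix(v))
  if (!all(dim(v) == dim(image)[1:2])) {
    stop("explanation shape does not match the image", call. = FALSE)
  }
  w <- pmax(v, 0)
  out <- image
  for (ch in 1:3) out[, , ch] <- image[, , ch] * w
  out
}
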