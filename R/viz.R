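#' Overlay rendering style
#'
#' Explanations are rendered by alpha-blending a positive hue (green by
#' default) over pixels with positive importance and a negative hue (red)
#' over pixels with negative importance. The blend weight is
#' `max_alpha * |value|^gamma`, so brighter colour means higher importance
#' and zero-importance pixels show the unmodified image.
#'
#' @param positive,negative RGB triples for the positive/negative hues.
#' @param gamma Exponent of the alpha rule (> 0).
#' @param max_alpha Maximum blend weight in `[0, 1]`.
#' @return A list of class `xw_overlay_style`.
#' @export
overlay_style <- function(positive = c(0, 1, 0), negative = c(1, 0, 0),
                          gamma = 1, max_alpha = 0.8) {
  stopifnot(max_alpha >= 0, max_alpha <= 1, gamma > 0)
  structure(list(positive = positive, negative = negative,
                 gamma = gamma, max_alpha = max_alpha),
            class = "xw_overlay_style")
}

#' Render an explanation over its image
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param explanation An `xw_importance` (typically smoothed) or `H x W`
#'   matrix in `[-1, 1]`.
#' @param style An [overlay_style()].
#' @return `H x W x 3` array in `[0, 1]`.
#' @export
render_overlay <- function(image, explanation, style = overlay_style()) {
  image <- as_raw_image(image, min_side = 1L)
  v <- if (inherits(explanation, "xw_importance")) explanation$values
       else explanation
  if (!all(dim(v) == dim(image)[1:2])) {
    stop("explanation shape does not match the image", call. = FALSE)
  }
  a_pos <- style$max_alpha * pmax(v, 0)^style$gamma
  a_neg <- style$max_alpha * pmax(-v, 0)^style$gamma
  out <- image
  for (ch in 1:3) {
    out[, , ch] <- image[, , ch] * (1 - a_pos - a_neg) +
      style$positive[ch] * a_pos + style$negative[ch] * a_neg
  }
  clamp01(out)
}

#' @export
#' @rdname autoplot_xwclust
autoplot.xw_importance <- function(object, ...) {
  v <- object$values
  df <- tibble::tibble(
    row = rep(seq_len(nrow(v)), times = ncol(v)),
    col = rep(seq_len(ncol(v)), each = nrow(v)),
    value = as.vector(v)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "red", mid = "black", high = "green",
                                  limits = c(-1, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Importance map (%s)", object$stage),
                  x = NULL, y = NULL, fill = "importance") +
    ggplot2::theme_minimal()
}

#' Autoplot methods
#'
#' `autoplot()` turns package result objects into ggplot2 figures: importance
#' maps as signed red/green rasters, cluster fits as scatter plots in the
#' first two reduced dimensions.
#'
#' @param object A package result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot_xwclust
NULL

#' Tile images into one gallery array
#'
#' @param images List of equally sized `H x W x 3` arrays.
#' @param ncol Number of tiles per row.
#' @param pad Pixels of black padding between tiles.
#' @return A single `H' x W' x 3` array.
#' @export
tile_images <- function(images, ncol = 4L, pad = 2L) {
  stopifnot(length(images) >= 1)
  d <- dim(images[[1]])
  nr <- ceiling(length(images) / ncol)
  out <- array(0, c(nr * d[1] + (nr - 1) * pad,
                    ncol * d[2] + (ncol - 1) * pad, 3))
  for (i in seq_along(images)) {
    r <- (i - 1) %/% ncol
    c0 <- (i - 1) %% ncol
    out[r * (d[1] + pad) + seq_len(d[1]),
        c0 * (d[2] + pad) + seq_len(d[2]), ] <- images[[i]]
  }
  out
}
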