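#' Generate a procedural mucosa-like background
#'
#' Produces a smooth, low-frequency pink/red texture emulating endoscopy
#' frames: correlated noise on a coarse grid is bilinearly upsampled and mapped
#' onto a dark-red-to-pink colour ramp, with a little fine-grained noise on
#' top. Optionally a green-dominated "picture-in-picture" inset is drawn in the
#' bottom-left corner, mimicking the scope-position overlay that acts as a
#' confounder in real colonoscopy data.
#'
#' @param height,width Output dimensions in pixels (at least 8).
#' @param seed Integer seed; the output is a deterministic function of
#'   `(height, width, seed, with_pip)`.
#' @param with_pip Draw the green picture-in-picture inset?
#' @return An `H x W x 3` array in `[0, 1]`.
#' @export
generate_background <- function(height, width, seed = 1L, with_pip = FALSE) {
  if (height < 8 || width < 8) {
    stop("background dimensions must be at least 8 x 8", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    t <- upsample_bilinear(
      matrix(runif(max(4, ceiling(height / 8)) * max(4, ceiling(width / 8))),
             max(4, ceiling(height / 8))),
      height, width
    )
    t <- rescale01(t)
    dark <- c(0.45, 0.13, 0.12)
    light <- c(0.97, 0.62, 0.58)
    img <- array(0, dim = c(height, width, 3))
    for (ch in 1:3) {
      img[, , ch] <- dark[ch] + t * (light[ch] - dark[ch]) +
        (runif(height * width) - 0.5) * 0.04
    }
    if (with_pip) {
      ph <- max(2L, round(0.25 * height))
      pw <- max(2L, round(0.25 * width))
      rows <- (height - ph + 1):height
      cols <- 1:pw
      g <- rescale01(upsample_bilinear(matrix(runif(16), 4), ph, pw))
      base <- c(0.10, 0.55, 0.22)
      for (ch in 1:3) {
        img[rows, cols, ch] <- base[ch] * (0.85 + 0.3 * g)
      }
    }
    clamp01(img)
  })
}

rescale01 <- function(m) {
  r <- range(m)
  if (r[2] - r[1] < .Machine$double.eps) return(m * 0)
  (m - r[1]) / (r[2] - r[1])
}

# Separable bilinear upsampling of a matrix to H x W (pixel-center aligned).
upsample_bilinear <- function(m, H, W) {
  sample_axis <- function(n_out, n_in) {
    p <- pmin(pmax(((seq_len(n_out) - 0.5) / n_out) * n_in + 0.5, 1), n_in)
    i0 <- pmin(floor(p), n_in - 1L)
    if (n_in == 1L) i0 <- rep(1, n_out)
    list(i0 = i0, i1 = pmin(i0 + 1, n_in), w = p - i0)
  }
  ry <- sample_axis(H, nrow(m))
  rx <- sample_axis(W, ncol(m))
  a <- m[ry$i0, , drop = FALSE] * (1 - ry$w) + m[ry$i1, , drop = FALSE] * ry$w
  a[, rx$i0, drop = FALSE] * rep(1 - rx$w, each = H) +
    a[, rx$i1, drop = FALSE] * rep(rx$w, each = H)
}
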