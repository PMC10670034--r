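#' Build a pseudo-real image dataset with ground-truth overlay masks
#'
#' Generates `n_total` square images: procedurally textured backgrounds for the
#' healthy class and, for the pathological class, the same kind of backgrounds
#' carrying exactly one coloured shape overlay drawn from `shapes`. Ground
#' truth (binary label, shape subtype, pixel mask) is recorded for every
#' image, so the downstream explanations and clusters can be scored against
#' what was actually drawn. Everything is a deterministic function of `seed`.
#'
#' @param out_dir Output directory (created if needed). Images and masks are
#'   written as 8-bit PNGs alongside a `manifest.csv` / `manifest.json`.
#' @param n_total Number of images (>= 4).
#' @param side Image side length in pixels.
#' @param pathology_rate Probability (or exact fraction under `stratified`)
#'   that an image is pathological.
#' @param shapes Character vector of [shape_palette()] names; each pathological
#'   image receives one shape drawn from these.
#' @param shape_rates Sampling rates over `shapes` (default equal).
#' @param size_fraction_range Range for the shape width/height as a fraction of
#'   the image dimensions (each sampled independently and uniformly).
#' @param splits Named fractions for `train`/`val`/`test`; must sum to 1.
#' @param seed Integer master seed.
#' @param pip_rate Probability of the green picture-in-picture confounder.
#' @param stratified If `TRUE`, class and subtype counts are exact (rounded)
#'   rather than binomially sampled.
#' @param background_dir Optional directory of real background images (PNG);
#'   when supplied, backgrounds are sampled from it (cropped bottom-left to a
#'   square and resized) instead of being generated procedurally.
#' @return The manifest as a tibble (invisibly carries `out_dir` in attribute
#'   `dir`): columns `id`, `image_path`, `mask_path`, `label`, `subtype`,
#'   `split`, `seed`, `pip`.
#' @export
build_dataset <- function(out_dir,
                          n_total,
                          side = 64L,
                          pathology_rate = 0.5,
                          shapes = c("yellow_rect", "blue_ellipse"),
                          shape_rates = NULL,
                          size_fraction_range = c(0.20, 0.25),
                          splits = c(train = 0.64, val = 0.16, test = 0.20),
                          seed = 1L,
                          pip_rate = 0.3,
                          stratified = FALSE,
                          background_dir = NULL) {
  stopifnot(n_total >= 4, pathology_rate > 0, pathology_rate < 1,
            length(shapes) >= 1,
            length(size_fraction_range) == 2,
            size_fraction_range[1] > 0, size_fraction_range[2] < 1,
            abs(sum(splits) - 1) < 1e-8)
  palette <- shape_palette()
  if (!all(shapes %in% names(palette))) {
    stop("unknown shape(s): ",
         paste(setdiff(shapes, names(palette)), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(shape_rates)) shape_rates <- rep(1 / length(shapes), length(shapes))
  stopifnot(length(shape_rates) == length(shapes), all(shape_rates > 0))
  shape_rates <- shape_rates / sum(shape_rates)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  bg_files <- if (!is.null(background_dir)) {
    list.files(background_dir, pattern = "\\.png$", full.names = TRUE)
  }

  manifest <- withr::with_seed(as.integer(seed), {
    n <- as.integer(n_total)
    if (stratified) {
      n_path <- round(pathology_rate * n)
      is_path <- rep(FALSE, n)
      is_path[sample.int(n, n_path)] <- TRUE
    } else {
      is_path <- runif(n) < pathology_rate
    }
    n_path <- sum(is_path)
    subtype <- rep("none", n)
    if (stratified) {
      counts <- floor(shape_rates * n_path)
      rem <- n_path - sum(counts)
      if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
      subtype[is_path] <- sample(rep(shapes, counts))
    } else {
      subtype[is_path] <- sample(shapes, n_path, replace = TRUE,
                                 prob = shape_rates)
    }
    pip <- runif(n) < pip_rate
    bg_seed <- sample.int(.Machine$integer.max - 1L, n)

    split <- character(n)
    ord <- sample.int(n)
    n_train <- round(splits[["train"]] * n)
    n_val <- round(splits[["val"]] * n)
    split[ord[seq_len(n_train)]] <- "train"
    split[ord[n_train + seq_len(n_val)]] <- "val"
    split[split == ""] <- "test"

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      bg <- if (is.null(bg_files)) {
        generate_background(side, side, seed = bg_seed[i], with_pip = pip[i])
      } else {
        crop_and_resize(read_image_png(bg_files[1 + (bg_seed[i] %% length(bg_files))]),
                        side)
      }
      bg <- quantize8(bg)
      img_path <- file.path("images", sprintf("img_%05d.png", i))
      mask_path <- NA_character_
      if (is_path[i]) {
        pal <- palette[[subtype[i]]]
        sf <- runif(2, size_fraction_range[1], size_fraction_range[2])
        coef <- if (pal$kind == "blob") draw_blob_coef()
        spec0 <- shape_spec(pal$kind, pal$color, size_fraction = sf,
                            blob_coef = coef)
        ext <- shape_extent(spec0, side, side)
        cx <- runif(1, ext[1], side - ext[1])
        cy <- runif(1, ext[2], side - ext[2])
        spec0$position <- c(cy / side, cx / side)
        res <- overlay_shape(bg, spec0)
        bg <- res$image
        mask_path <- file.path("masks", sprintf("mask_%05d.png", i))
        write_mask_png(res$mask, file.path(out_dir, mask_path))
      }
      write_image_png(bg, file.path(out_dir, img_path))
      rows[[i]] <- tibble::tibble(
        id = sprintf("img_%05d", i),
        image_path = img_path,
        mask_path = mask_path,
        label = if (is_path[i]) "pathological" else "healthy",
        subtype = subtype[i],
        split = split[i],
        seed = bg_seed[i],
        pip = pip[i]
      )
    }
    dplyr::bind_rows(rows)
  })

  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", na = "null", pretty = TRUE)
  attr(manifest, "dir") <- normalizePath(out_dir)
  manifest
}

#' Read a dataset manifest
#'
#' @param path A dataset directory (containing `manifest.csv`) or the CSV path.
#' @return The manifest tibble with attribute `dir` set.
#' @export
read_manifest <- function(path) {
  csv <- if (dir.exists(path)) file.path(path, "manifest.csv") else path
  m <- readr::read_csv(csv, show_col_types = FALSE)
  attr(m, "dir") <- normalizePath(dirname(csv))
  m
}

#' Load manifest images into memory
#'
#' @param manifest Manifest tibble from [build_dataset()] / [read_manifest()].
#' @param split Optional split filter (`"train"`, `"val"`, `"test"`).
#' @return List with `x` (`H x W x 3 x n` array), `y` (0 = healthy,
#'   1 = pathological), `subtype`, `id` and the row-filtered manifest.
#' @export
load_images <- function(manifest, split = NULL) {
  dir <- attr(manifest, "dir")
  if (is.null(dir)) stop("manifest carries no dataset directory", call. = FALSE)
  m <- manifest
  if (!is.null(split)) m <- dplyr::filter(m, .data$split %in% .env$split)
  if (nrow(m) == 0) stop("no images in requested split", call. = FALSE)
  imgs <- lapply(file.path(dir, m$image_path), read_image_png)
  d <- dim(imgs[[1]])
  x <- array(unlist(imgs, use.names = FALSE), dim = c(d, length(imgs)))
  list(x = x, y = as.integer(m$label == "pathological"),
       subtype = m$subtype, id = m$id, manifest = m)
}

#' Load ground-truth masks for pathological records
#'
#' @inheritParams load_images
#' @return Named list of logical matrices keyed by image id.
#' @export
load_masks <- function(manifest, split = NULL) {
  dir <- attr(manifest, "dir")
  m <- manifest
  if (!is.null(split)) m <- dplyr::filter(m, .data$split %in% .env$split)
  m <- dplyr::filter(m, !is.na(.data$mask_path))
  out <- lapply(file.path(dir, m$mask_path), read_mask_png)
  names(out) <- m$id
  out
}
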