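# Shared fixtures, built lazily on first use and cached for the session.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, builder(), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# Full desk-scale benchmark runs (the two bundled subtype pairs).
benchmark_run <- function(variant) {
  cached(paste0("run_", variant), function() {
    dir <- file.path(tempdir(), paste0("xwclust_bench_", variant))
    res <- suppressMessages(run_pipeline(benchmark_config(variant), dir))
    res$out_dir <- dir
    res
  })
}

# Small dataset + quickly trained model for contract-level tests.
tiny_dataset <- function() {
  cached("tiny_dataset", function() {
    build_dataset(file.path(tempdir(), "xwclust_tiny_ds"), n_total = 80,
                  side = 32, seed = 7, stratified = TRUE)
  })
}

tiny_model <- function() {
  cached("tiny_model", function() {
    suppressMessages(train_classifier(
      tiny_dataset(),
      config = train_config(lr = 0.01, batch_size = 16, max_epochs = 4,
                            seed = 3),
      channels = c(4L, 8L, 16L), augment_training = FALSE
    ))
  })
}

# A deterministic toy classifier: mean of the red channel.
red_mean_classifier <- function(image) mean(image[, , 1])

# Flat mid-gray test image helper.
flat_image <- function(side, value = 0.5) array(value, c(side, side, 3))
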