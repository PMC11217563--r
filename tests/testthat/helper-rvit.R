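# Shared test fixtures: all built in code, no stored data.

# Square random image in [0, 1].
rand_image <- function(side, channels = 1L, seed = NULL) {
  gen <- function() {
    if (channels == 1L) matrix(stats::runif(side * side), side, side)
    else array(stats::runif(side * side * channels),
               dim = c(side, side, channels))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Desk-scale model configuration used across tests.
small_config <- function(preset = "rvit", channels = 1L, ...) {
  model_config(preset = preset, image_size = 64L, patch_size = 8L,
               embed_dim = 64L, depth = 4L, heads = 4L, mlp_size = 128L,
               channels = channels, ...)
}

# Very small configuration for fast structural tests.
tiny_config <- function(preset = "rvit", channels = 1L, ...) {
  model_config(preset = preset, image_size = 16L, patch_size = 4L,
               embed_dim = 8L, depth = 2L, heads = 2L, mlp_size = 16L,
               channels = channels, ...)
}

# A model whose head is all-zero: logits are (0, 0) for every input, so the
# predicted class is constant (argmax tie -> first class).
zero_head_model <- function(cfg = tiny_config(), seed = 5L) {
  m <- build_model(cfg, seed = seed)
  m$params$head$W[] <- 0
  m$params$head$b[] <- 0
  m
}

# In-memory dataset from a list of images.
as_dataset <- function(images, labels, image_size = nrow(images[[1L]])) {
  structure(list(images = images, labels = as.integer(labels),
                 classes = c(negative = 0L, positive = 1L),
                 image_size = image_size),
            class = "rvit_dataset")
}
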