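# Model assembly: configuration presets, parameter initialisation, the
# batched forward pass (rotation set -> shared projection -> average ->
# class/position embeddings -> encoder -> head) and its hand-written backward
# pass, parameter counting and checkpointing.

#' Model configuration
#'
#' Builds a validated architecture configuration. Presets reproduce the
#' published hyperparameter tables: `"rvit"` (patch-embedding dimension 142,
#' depth 10, 10 heads, MLP size 480, rotation averaging over k = 4 quarter
#' turns, depth-wise convolution stem), `"base_vit"` (dimension 768, depth 12,
#' 12 heads, MLP size 1024, no rotation averaging, no stem),
#' `"rvit_variant1"` (rvit without rotation averaging) and `"rvit_variant2"`
#' (rvit without the depth-wise stem). Any field can be overridden, e.g. to
#' scale the model down for desk-size experiments.
#'
#' @param preset One of `"rvit"`, `"base_vit"`, `"rvit_variant1"`,
#'   `"rvit_variant2"`, or `NULL` for a fully manual configuration.
#' @param image_size Input side length in pixels (images are square).
#' @param patch_size Patch side length P; must divide `image_size`.
#' @param embed_dim Token dimension D.
#' @param depth Number of encoder layers L.
#' @param heads Attention heads h.
#' @param mlp_size MLP hidden width.
#' @param attention_dropout Dropout rate on attention weights (training only).
#' @param rotations Rotation count k in {1, 2, 4}.
#' @param use_rotated_embedding If `FALSE`, the rotation set collapses to the
#'   unrotated image (k effectively 1).
#' @param use_depthwise_stem If `TRUE`, a depth-wise + pointwise convolution
#'   stem is applied to each rotated copy before patch extraction.
#' @param channels Input channel count C.
#' @param stem_channels Stem output width; defaults to `channels`.
#' @param normalize_input If `TRUE` (default), inputs in \[0, 1\] are
#'   centred to \[-1, 1\] (`(x - 0.5) / 0.5`, the usual mean-0.5/std-0.5
#'   intensity normalisation) before the stem and patch embedding. Pointwise,
#'   so it commutes with rotation and leaves the invariance intact.
#' @param num_classes Output classes (fixed at 2 for this problem).
#' @return Object of class `rvit_config` (a named list).
#' @export
model_config <- function(preset = NULL,
                         image_size = 224L, patch_size = 16L,
                         embed_dim = 142L, depth = 10L, heads = 10L,
                         mlp_size = 480L, attention_dropout = 0.1,
                         rotations = 4L, use_rotated_embedding = TRUE,
                         use_depthwise_stem = TRUE,
                         channels = 3L, stem_channels = channels,
                         normalize_input = TRUE,
                         num_classes = 2L) {
  cfg <- list(image_size = as.integer(image_size),
              patch_size = as.integer(patch_size),
              embed_dim = as.integer(embed_dim),
              depth = as.integer(depth),
              heads = as.integer(heads),
              mlp_size = as.integer(mlp_size),
              attention_dropout = attention_dropout,
              rotations = as.integer(rotations),
              use_rotated_embedding = isTRUE(use_rotated_embedding),
              use_depthwise_stem = isTRUE(use_depthwise_stem),
              channels = as.integer(channels),
              stem_channels = as.integer(stem_channels),
              normalize_input = isTRUE(normalize_input),
              num_classes = as.integer(num_classes),
              preset = preset)
  if (!is.null(preset)) {
    mc <- match.call()
    given <- names(mc)[-1L]
    presets <- list(
      rvit = list(embed_dim = 142L, depth = 10L, heads = 10L,
                  mlp_size = 480L, rotations = 4L,
                  use_rotated_embedding = TRUE, use_depthwise_stem = TRUE),
      base_vit = list(embed_dim = 768L, depth = 12L, heads = 12L,
                      mlp_size = 1024L, rotations = 1L,
                      use_rotated_embedding = FALSE,
                      use_depthwise_stem = FALSE),
      rvit_variant1 = list(embed_dim = 142L, depth = 10L, heads = 10L,
                           mlp_size = 480L, rotations = 1L,
                           use_rotated_embedding = FALSE,
                           use_depthwise_stem = TRUE),
      rvit_variant2 = list(embed_dim = 142L, depth = 10L, heads = 10L,
                           mlp_size = 480L, rotations = 4L,
                           use_rotated_embedding = TRUE,
                           use_depthwise_stem = FALSE))
    if (!preset %in% names(presets)) {
      stop(sprintf("unknown preset '%s'; available: %s", preset,
                   paste(names(presets), collapse = ", ")), call. = FALSE)
    }
    for (field in names(presets[[preset]])) {
      if (!field %in% given) cfg[[field]] <- presets[[preset]][[field]]
    }
    if (!"stem_channels" %in% given && !"channels" %in% given) {
      cfg$stem_channels <- cfg$channels
    }
  }
  if (cfg$image_size %% cfg$patch_size != 0L) {
    stop(sprintf("image_size %d is not divisible by patch_size %d",
                 cfg$image_size, cfg$patch_size), call. = FALSE)
  }
  if (!cfg$rotations %in% c(1L, 2L, 4L)) {
    stop(sprintf("rotations must be one of 1, 2, 4 (got %d)", cfg$rotations),
         call. = FALSE)
  }
  if (cfg$heads < 1L || cfg$heads > cfg$embed_dim) {
    stop("heads must be between 1 and embed_dim", call. = FALSE)
  }
  if (cfg$num_classes != 2L) {
    stop("only binary classification (num_classes = 2) is supported",
         call. = FALSE)
  }
  structure(cfg, class = "rvit_config")
}

# Number of non-class tokens.
n_patches <- function(cfg) (cfg$image_size %/% cfg$patch_size)^2

# Effective rotation count used by the forward pass.
effective_k <- function(cfg) if (cfg$use_rotated_embedding) cfg$rotations else 1L

init_params <- function(cfg) {
  D <- cfg$embed_dim
  N <- n_patches(cfg)
  cs <- if (cfg$use_depthwise_stem) cfg$stem_channels else cfg$channels
  pdim <- cfg$patch_size^2 * cs
  params <- list()
  if (cfg$use_depthwise_stem) {
    params$stem <- unclass(new_depthwise_stem(cfg$channels, cfg$stem_channels))
  }
  params$proj <- unclass(new_patch_projector(pdim, D))
  params$cls <- stats::rnorm(D, sd = 0.02)
  params$pos <- matrix(stats::rnorm((N + 1L) * D, sd = 0.02), N + 1L, D)
  layers <- lapply(seq_len(cfg$depth), function(l) {
    unclass(new_encoder_layer(D, cfg$heads, cfg$mlp_size,
                              attn_dropout = cfg$attention_dropout))
  })
  names(layers) <- paste0("layer", seq_len(cfg$depth))
  params$layers <- layers
  params$lnf_g <- rep(1, D)
  params$lnf_b <- numeric(D)
  params$head <- unclass(new_classifier_head(D, cfg$num_classes))
  params
}

#' Build a model from a configuration
#'
#' Initialises all trainable parameters (normal, sd 0.02; layer-norm scales 1;
#' biases 0; the depth-wise stem starts near the identity map). The forward
#' pass is: optional stem on each rotated copy -> rotation set (k copies) ->
#' patch extraction -> shared linear projection -> elementwise average over
#' rotations -> class token + position embeddings -> L pre-norm encoder layers
#' -> final layer norm -> softmax head on the class token.
#'
#' @param config An [model_config()] object, or a preset name.
#' @param seed Optional integer seed for reproducible initialisation.
#' @return Object of class `rvit_model` with elements `config` and `params`.
#' @export
build_model <- function(config, seed = NULL) {
  if (is.character(config)) config <- model_config(preset = config)
  stopifnot(inherits(config, "rvit_config"))
  params <- if (is.null(seed)) init_params(config) else {
    withr::with_seed(as.integer(seed), init_params(config))
  }
  structure(list(config = config, params = params), class = "rvit_model")
}

# ---- trainable-parameter bookkeeping ----------------------------------------

# Fields of layer lists that are hyperparameters, not weights.
.non_param_fields <- c("heads", "head_dim", "attn_dropout")

# Paths (character vectors of names) of every trainable array in a nested
# parameter list. All sub-lists are named by construction.
param_paths <- function(x, prefix = character()) {
  if (is.list(x)) {
    out <- list()
    for (nm in names(x)) {
      if (nm %in% .non_param_fields) next
      out <- c(out, param_paths(x[[nm]], c(prefix, nm)))
    }
    out
  } else if (is.numeric(x)) {
    list(prefix)
  } else {
    list()
  }
}

get_leaf <- function(x, path) {
  for (k in path) x <- x[[k]]
  x
}

set_leaf <- function(x, path, value) {
  if (length(path) == 1L) {
    x[[path]] <- value
  } else {
    x[[path[1L]]] <- set_leaf(x[[path[1L]]], path[-1L], value)
  }
  x
}

#' Count trainable parameters
#'
#' Total number of trainable scalars in a model. Rotation averaging adds no
#' parameters (the projector is shared across rotations), so the count is
#' independent of the rotation count k; the depth-wise stem adds its kernel,
#' mixing and bias parameters.
#'
#' @param model An `rvit_model`.
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "rvit_model"))
  paths <- param_paths(model$params)
  sum(vapply(paths, function(p) length(get_leaf(model$params, p)), numeric(1)))
}

# ---- forward / backward ------------------------------------------------------

# Replicate a grayscale image to the channel count the model expects.
conform_image <- function(img, cfg) {
  a <- as_image_array(img)
  d <- dim(a)
  if (d[1L] != cfg$image_size || d[2L] != cfg$image_size) {
    stop(sprintf("image is %d x %d but the model expects %d x %d",
                 d[1L], d[2L], cfg$image_size, cfg$image_size), call. = FALSE)
  }
  if (d[3L] == cfg$channels) return(a)
  if (d[3L] == 1L) {
    return(array(rep(a, cfg$channels), dim = c(d[1L], d[2L], cfg$channels)))
  }
  if (d[3L] > cfg$channels) return(a[, , seq_len(cfg$channels), drop = FALSE])
  stop(sprintf("image has %d channels but the model expects %d",
               d[3L], cfg$channels), call. = FALSE)
}

# Batched forward pass. images: list of H x W (x C) arrays.
# Returns logits (B x 2), probs, and (optionally) the cache for backward.
model_forward <- function(model, images, training = FALSE, want_cache = FALSE) {
  cfg <- model$config
  pp <- model$params
  if (!is.list(images)) images <- list(images)
  B <- length(images)
  k <- effective_k(cfg)
  N <- n_patches(cfg)
  T <- N + 1L
  D <- cfg$embed_dim
  cs <- if (cfg$use_depthwise_stem) cfg$stem_channels else cfg$channels
  pdim <- cfg$patch_size^2 * cs
  P_all <- matrix(0, B * k * N, pdim)
  stem_caches <- if (cfg$use_depthwise_stem && want_cache) {
    vector("list", B * k)
  } else NULL
  row0 <- 0L
  for (b in seq_len(B)) {
    img <- conform_image(images[[b]], cfg)
    if (cfg$normalize_input) img <- (img - 0.5) * 2
    rset <- make_rotation_set(img, k)
    for (j in seq_len(k)) {
      x <- rset$images[[j]]
      if (cfg$use_depthwise_stem) {
        sf <- stem_forward(x, pp$stem)
        if (!is.null(stem_caches)) stem_caches[[(b - 1L) * k + j]] <- sf
        x <- sf$out
      }
      P_all[(row0 + 1L):(row0 + N), ] <- extract_patches(x, cfg$patch_size)
      row0 <- row0 + N
    }
  }
  Zall <- P_all %*% pp$proj$W
  # average over the k rotated copies of each image, then add the shared bias
  if (k == 1L) {
    Z <- Zall
  } else {
    Z <- matrix(0, B * N, D)
    for (j in 0:(k - 1L)) {
      idx <- as.vector(outer(seq_len(N), (seq_len(B) - 1L) * k * N + j * N, "+"))
      Z <- Z + Zall[idx, , drop = FALSE]
    }
    Z <- Z / k
  }
  Z <- add_bias(Z, pp$proj$b)
  clsrows <- (seq_len(B) - 1L) * T + 1L
  tokidx <- as.vector(outer(2:T, (seq_len(B) - 1L) * T, "+"))
  X <- matrix(0, B * T, D)
  X[clsrows, ] <- rep(pp$cls, each = B)
  X[tokidx, ] <- Z
  X <- X + pp$pos[rep(seq_len(T), B), , drop = FALSE]
  layer_caches <- if (want_cache) vector("list", cfg$depth) else NULL
  for (l in seq_len(cfg$depth)) {
    bf <- encoder_block_forward(X, pp$layers[[l]], B = B, T = T,
                                training = training, want_cache = want_cache)
    if (want_cache) layer_caches[[l]] <- bf$cache
    X <- bf$x
  }
  lnf <- layer_norm_forward(X, pp$lnf_g, pp$lnf_b)
  h_cls <- lnf$y[clsrows, , drop = FALSE]
  logits <- add_bias(h_cls %*% pp$head$W, pp$head$b)
  probs <- softmax_rows(logits)
  cache <- NULL
  if (want_cache) {
    cache <- list(P_all = P_all, stem_caches = stem_caches,
                  layer_caches = layer_caches, lnf = lnf, h_cls = h_cls,
                  clsrows = clsrows, tokidx = tokidx,
                  B = B, T = T, N = N, k = k)
  }
  list(logits = logits, probs = probs, cache = cache)
}

# Backward pass. dlogits: B x 2 gradient at the logits. Returns nested
# parameter gradients mirroring model$params, and the gradient at the input
# of the last encoder layer (used by Grad-CAM).
model_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  pp <- model$params
  B <- cache$B; T <- cache$T; N <- cache$N; k <- cache$k
  D <- cfg$embed_dim
  grads <- list()
  grads$head <- list(W = crossprod(cache$h_cls, dlogits),
                     b = colSums(dlogits))
  dXf <- matrix(0, B * T, D)
  dXf[cache$clsrows, ] <- dlogits %*% t(pp$head$W)
  lnfb <- layer_norm_backward(dXf, cache$lnf, pp$lnf_g)
  grads$lnf_g <- lnfb$dg
  grads$lnf_b <- lnfb$db
  dX <- lnfb$dx
  layer_grads <- vector("list", cfg$depth)
  last_input_act <- NULL
  last_input_grad <- NULL
  for (l in rev(seq_len(cfg$depth))) {
    bb <- encoder_block_backward(dX, cache$layer_caches[[l]], pp$layers[[l]])
    layer_grads[[l]] <- bb$grads
    dX <- bb$dx
    if (l == cfg$depth) {
      last_input_act <- cache$layer_caches[[l]]$x
      last_input_grad <- bb$dx
    }
  }
  names(layer_grads) <- names(pp$layers)
  grads$layers <- layer_grads
  # embedding stage
  grads$pos <- rowsum(dX, rep(seq_len(T), B), reorder = TRUE)
  grads$cls <- colSums(dX[cache$clsrows, , drop = FALSE])
  dZ <- dX[cache$tokidx, , drop = FALSE]
  grads$proj <- list(W = NULL, b = colSums(dZ))
  zmap <- rep((seq_len(B) - 1L) * N, each = k * N) + rep(seq_len(N), times = B * k)
  dZrep <- dZ[zmap, , drop = FALSE] / k
  grads$proj$W <- crossprod(cache$P_all, dZrep)
  if (cfg$use_depthwise_stem) {
    dR <- dZrep %*% t(pp$proj$W)
    sg <- list(dw = array(0, dim = dim(pp$stem$dw)),
               dw_bias = numeric(length(pp$stem$dw_bias)),
               pw = matrix(0, nrow(pp$stem$pw), ncol(pp$stem$pw)),
               pw_bias = numeric(length(pp$stem$pw_bias)))
    H <- cfg$image_size
    cs <- cfg$stem_channels
    for (t in seq_len(B * k)) {
      rows <- ((t - 1L) * N + 1L):(t * N)
      dfeat <- reassemble_patches(dR[rows, , drop = FALSE], H, H, cs,
                                  patch_size = cfg$patch_size)
      g <- stem_backward(dfeat, cache$stem_caches[[t]], pp$stem)
      sg$dw <- sg$dw + g$dw
      sg$dw_bias <- sg$dw_bias + g$dw_bias
      sg$pw <- sg$pw + g$pw
      sg$pw_bias <- sg$pw_bias + g$pw_bias
    }
    grads$stem <- sg
  }
  # order grads like params for the optimiser walk
  grads <- grads[intersect(names(pp), names(grads))]
  list(grads = grads,
       last_input_act = last_input_act, last_input_grad = last_input_grad)
}

#' Compute class logits for one or more images
#'
#' Runs the forward pass in evaluation mode (no dropout).
#'
#' @param model An `rvit_model`.
#' @param images A single image (matrix or H x W x C array) or a list of
#'   images.
#' @return B x 2 matrix of logits, column order (non-tumor, tumor).
#' @export
model_logits <- function(model, images) {
  model_forward(model, images, training = FALSE)$logits
}

#' Predict classes or probabilities
#'
#' @param object An `rvit_model`.
#' @param newdata A single image, a list of images, or an `rvit_dataset`.
#' @param type `"class"` for 0/1 labels (argmax; 1 = tumor/positive) or
#'   `"prob"` for a B x 2 matrix of probabilities.
#' @param batch_size Images per forward batch.
#' @param ... Unused.
#' @return Integer vector of labels or a probability matrix.
#' @export
predict.rvit_model <- function(object, newdata, type = c("class", "prob"),
                               batch_size = 32L, ...) {
  type <- match.arg(type)
  images <- if (inherits(newdata, "rvit_dataset")) newdata$images
            else if (is.list(newdata)) newdata else list(newdata)
  n <- length(images)
  probs <- matrix(0, n, object$config$num_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    probs[i:j, ] <- model_forward(object, images[i:j],
                                  training = FALSE)$probs
    i <- j + 1L
  }
  if (type == "prob") probs else max.col(probs, ties.method = "first") - 1L
}

#' @export
print.rvit_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<rvit_model%s> %dx%d/%d patches, D=%d, L=%d, h=%d, mlp=%d, k=%s, stem=%s\n",
    if (is.null(cfg$preset)) "" else paste0(" preset=", cfg$preset),
    cfg$image_size, cfg$image_size, cfg$patch_size, cfg$embed_dim, cfg$depth,
    cfg$heads, cfg$mlp_size,
    if (cfg$use_rotated_embedding) cfg$rotations else "1 (rotation averaging off)",
    if (cfg$use_depthwise_stem) "on" else "off"))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single self-describing file holding the configuration
#' and all weights; the configuration round-trips losslessly.
#'
#' @param model An `rvit_model`.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `rvit_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "rvit_model"))
  saveRDS(list(config = unclass(model$config), params = model$params,
               format = "rvit_checkpoint_v1"), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("checkpoint file not found: %s", path), call. = FALSE)
  }
  ck <- readRDS(path)
  if (!identical(ck$format, "rvit_checkpoint_v1")) {
    stop("not a recognised checkpoint file", call. = FALSE)
  }
  structure(list(config = structure(ck$config, class = "rvit_config"),
                 params = ck$params), class = "rvit_model")
}
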