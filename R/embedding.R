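# Patch embedding: shared linear projection, rotation averaging, class token
# and position embeddings, optional depth-wise convolution stem.

# Fast row-broadcast bias add (hot path).
add_bias <- function(m, b) m + rep(b, each = nrow(m))

#' Create a linear patch projector
#'
#' The projector is the embedding matrix `E` (with a bias vector) that maps a
#' flattened patch of length `input_dim = P^2 * C` to a `embed_dim`-dimensional
#' token. A single projector instance is shared by all rotated copies of an
#' image.
#'
#' @param input_dim Flattened patch length (P^2 * C).
#' @param embed_dim Token dimension D.
#' @param sd Optional standard deviation for normal initialisation; by
#'   default weights are fan-in scaled uniform (U(-1/sqrt(fan_in),
#'   1/sqrt(fan_in))), the standard affine-layer initialisation.
#' @return An object of class `patch_projector` with elements `W`
#'   (input_dim x embed_dim) and `b` (length embed_dim).
#' @export
new_patch_projector <- function(input_dim, embed_dim, sd = NULL) {
  structure(
    list(W = init_weight(input_dim, embed_dim, sd),
         b = numeric(embed_dim)),
    class = "patch_projector")
}

# Fan-in scaled uniform init (default) or normal with given sd.
init_weight <- function(fan_in, fan_out, sd = NULL) {
  if (is.null(sd)) {
    lim <- 1 / sqrt(fan_in)
    matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
  } else {
    matrix(stats::rnorm(fan_in * fan_out, sd = sd), fan_in, fan_out)
  }
}

#' Linearly embed a patch sequence
#'
#' Computes `tokens[i, ] = patches[i, ] %*% W + b` for the shared projector.
#'
#' @param patches N x (P^2 * C) patch matrix.
#' @param projector A [new_patch_projector()] object (or any list with `W`,
#'   `b`).
#' @return N x D token matrix.
#' @export
embed_patches <- function(patches, projector) {
  if (ncol(patches) != nrow(projector$W)) {
    stop(sprintf(
      "patch length %d does not match projector input size %d",
      ncol(patches), nrow(projector$W)), call. = FALSE)
  }
  add_bias(patches %*% projector$W, projector$b)
}

#' Average token sequences across rotations
#'
#' Elementwise arithmetic mean of `k` equally shaped token sequences, one per
#' rotated copy of the image. This is the step that confers exact quarter-turn
#' invariance: rotating the input permutes the set of rotated copies, leaving
#' the mean unchanged. No renormalisation is applied.
#'
#' @param per_rotation Non-empty list of N x D matrices.
#' @return N x D matrix of means.
#' @export
average_rotated_embeddings <- function(per_rotation) {
  if (!is.list(per_rotation) || length(per_rotation) == 0L) {
    stop("per_rotation must be a non-empty list of token matrices",
         call. = FALSE)
  }
  d0 <- dim(per_rotation[[1L]])
  for (z in per_rotation) {
    if (!identical(dim(z), d0)) {
      stop("all rotation embeddings must share the same shape", call. = FALSE)
    }
  }
  Reduce(`+`, per_rotation) / length(per_rotation)
}

#' Prepend the class token and add position embeddings
#'
#' @param tokens N x D token matrix (no class token).
#' @param class_token Length-D numeric vector (the learnable CLS token).
#' @param positions (N + 1) x D position-embedding table; row 1 corresponds to
#'   the class token.
#' @return (N + 1) x D matrix: `rbind(class_token, tokens) + positions`.
#' @export
add_class_and_positions <- function(tokens, class_token, positions) {
  if (nrow(positions) != nrow(tokens) + 1L) {
    stop(sprintf("position table has %d rows; expected N + 1 = %d",
                 nrow(positions), nrow(tokens) + 1L), call. = FALSE)
  }
  rbind(matrix(class_token, 1L), tokens) + positions
}

# ---- depth-wise convolution stem --------------------------------------------

# Shift a matrix by (dy, dx) with zero padding: out[y, x] = m[y + dy, x + dx]
# where defined, 0 elsewhere.
shift_zero <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  ys <- max(1L, 1L - dy):min(H, H - dy)
  xs <- max(1L, 1L - dx):min(W, W - dx)
  if (length(ys) > 0L && length(xs) > 0L) {
    out[ys, xs] <- m[ys + dy, xs + dx, drop = FALSE]
  }
  out
}

#' Create depth-wise convolution stem parameters
#'
#' The stem is a per-channel (depth-wise) k x k convolution followed by a
#' pointwise 1 x 1 channel-mixing map. Both steps are linear and
#' spatial-size preserving (zero "same" padding), so patch extraction
#' downstream is unchanged. With `init = "identity"` the stem is the exact
#' identity map (centre tap 1, identity mixing), useful for testing.
#'
#' @param channels Input channel count C.
#' @param out_channels Output channel count (stem width); defaults to C.
#' @param kernel_size Odd kernel side length (default 3).
#' @param init `"random"` or `"identity"`.
#' @param sd Weight init standard deviation for `init = "random"`.
#' @return Object of class `stem_params`: list with `dw` (k x k x C kernel),
#'   `dw_bias` (C), `pw` (C x out_channels), `pw_bias` (out_channels).
#' @export
new_depthwise_stem <- function(channels, out_channels = channels,
                               kernel_size = 3L,
                               init = c("random", "identity"), sd = 0.02) {
  init <- match.arg(init)
  ks <- as.integer(kernel_size)
  stopifnot(ks %% 2L == 1L)
  if (init == "identity") {
    stopifnot(out_channels == channels)
    dw <- array(0, dim = c(ks, ks, channels))
    ctr <- (ks + 1L) %/% 2L
    for (c in seq_len(channels)) dw[ctr, ctr, c] <- 1
    pw <- diag(1, channels, out_channels)
  } else {
    dw <- array(stats::rnorm(ks * ks * channels, sd = sd),
                dim = c(ks, ks, channels))
    # bias the centre tap towards identity so early training sees the image
    ctr <- (ks + 1L) %/% 2L
    for (c in seq_len(channels)) dw[ctr, ctr, c] <- dw[ctr, ctr, c] + 1
    pw <- diag(1, channels, out_channels) +
      matrix(stats::rnorm(channels * out_channels, sd = sd),
             channels, out_channels)
  }
  structure(list(dw = dw, dw_bias = numeric(channels), pw = pw,
                 pw_bias = numeric(out_channels)),
            class = "stem_params")
}

#' Apply the depth-wise convolution stem
#'
#' Per-channel k x k convolution (cross-correlation convention, zero "same"
#' padding) plus bias, then a pointwise 1 x 1 linear mix across channels. The
#' output has the same spatial size as the input and `ncol(pw)` channels.
#' Inside a rotation-averaged model the stem is applied independently to each
#' rotated copy, which preserves the exact quarter-turn invariance of the
#' averaged embedding.
#'
#' @param image H x W matrix or H x W x C array.
#' @param stem A [new_depthwise_stem()] object.
#' @return H x W x out_channels array of features.
#' @export
depthwise_stem <- function(image, stem) {
  stem_forward(image, stem)$out
}

# Forward pass keeping intermediates for backprop.
stem_forward <- function(image, stem) {
  img <- as_image_array(image)
  d <- dim(img)
  C <- d[3L]
  stopifnot(C == dim(stem$dw)[3L])
  ks <- dim(stem$dw)[1L]
  ctr <- (ks + 1L) %/% 2L
  mid <- array(0, dim = d)
  for (c in seq_len(C)) {
    acc <- matrix(stem$dw_bias[c], d[1L], d[2L])
    for (u in seq_len(ks)) {
      for (v in seq_len(ks)) {
        w <- stem$dw[u, v, c]
        if (w != 0) acc <- acc + w * shift_zero(img[, , c], u - ctr, v - ctr)
      }
    }
    mid[, , c] <- acc
  }
  n_out <- ncol(stem$pw)
  flat <- matrix(mid, d[1L] * d[2L], C)
  outf <- add_bias(flat %*% stem$pw, stem$pw_bias)
  out <- array(outf, dim = c(d[1L], d[2L], n_out))
  list(out = out, mid = mid, img = img)
}

# Gradients of the stem parameters given d(loss)/d(out). Input-image gradients
# are not needed (images are data) and are not computed.
stem_backward <- function(dout, cache, stem) {
  d <- dim(cache$img)
  C <- d[3L]
  n_out <- ncol(stem$pw)
  ks <- dim(stem$dw)[1L]
  ctr <- (ks + 1L) %/% 2L
  doutf <- matrix(dout, d[1L] * d[2L], n_out)
  midf <- matrix(cache$mid, d[1L] * d[2L], C)
  d_pw <- crossprod(midf, doutf)
  d_pwb <- colSums(doutf)
  dmidf <- doutf %*% t(stem$pw)
  d_dw <- array(0, dim = dim(stem$dw))
  d_dwb <- numeric(C)
  for (c in seq_len(C)) {
    dm <- matrix(dmidf[, c], d[1L], d[2L])
    d_dwb[c] <- sum(dm)
    for (u in seq_len(ks)) {
      for (v in seq_len(ks)) {
        d_dw[u, v, c] <- sum(shift_zero(cache$img[, , c], u - ctr, v - ctr) * dm)
      }
    }
  }
  list(dw = d_dw, dw_bias = d_dwb, pw = d_pw, pw_bias = d_pwb)
}
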