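# Transformer encoder: pre-norm residual blocks of multi-head self-attention
# and a GELU MLP, plus the softmax classification head.
#
# All block functions operate on a batch laid out as a single (B*T) x D
# matrix of B contiguous sequence blocks of T rows each; attention never mixes
# rows across blocks. Forward functions optionally keep the intermediates
# needed by the hand-written backward pass in train.R.

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

softmax_rows <- function(S) {
  e <- exp(S - apply(S, 1L, max))
  e / rowSums(e)
}

# Row-wise layer normalisation (population variance, eps inside the sqrt).
LN_EPS <- 1e-6

layer_norm_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  invstd <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * invstd
  list(y = add_bias(xhat * rep(g, each = nrow(x)), b),
       xhat = xhat, invstd = invstd)
}

layer_norm_backward <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- dy * rep(g, each = nrow(dy))
  dx <- cache$invstd *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

#' Create one transformer encoder layer's parameters
#'
#' A pre-norm block: layer norm, multi-head self-attention (with separate
#' query/key/value/output projections), residual add; then layer norm, a
#' two-layer GELU MLP of hidden width `mlp_size`, residual add. The per-head
#' dimension is `floor(embed_dim / heads)`; when `heads` does not divide
#' `embed_dim` the attention inner width is `heads * floor(embed_dim / heads)`
#' and the output projection maps back to `embed_dim`.
#'
#' @param embed_dim Token dimension D.
#' @param heads Number of attention heads h.
#' @param mlp_size Hidden width of the MLP.
#' @param attn_dropout Dropout rate applied to attention weights in training
#'   mode.
#' @param sd Optional normal-init standard deviation; fan-in scaled uniform
#'   by default.
#' @return Object of class `encoder_layer` (named list of weight arrays plus
#'   `heads`, `head_dim`, `attn_dropout`).
#' @export
new_encoder_layer <- function(embed_dim, heads, mlp_size,
                              attn_dropout = 0.1, sd = NULL) {
  head_dim <- embed_dim %/% heads
  stopifnot(head_dim >= 1L)
  inner <- heads * head_dim
  rn <- function(nr, nc) init_weight(nr, nc, sd)
  structure(list(
    Wq = rn(embed_dim, inner), bq = numeric(inner),
    Wk = rn(embed_dim, inner), bk = numeric(inner),
    Wv = rn(embed_dim, inner), bv = numeric(inner),
    Wo = rn(inner, embed_dim), bo = numeric(embed_dim),
    ln1_g = rep(1, embed_dim), ln1_b = numeric(embed_dim),
    ln2_g = rep(1, embed_dim), ln2_b = numeric(embed_dim),
    W1 = rn(embed_dim, mlp_size), b1 = numeric(mlp_size),
    W2 = rn(mlp_size, embed_dim), b2 = numeric(embed_dim),
    heads = as.integer(heads), head_dim = as.integer(head_dim),
    attn_dropout = attn_dropout), class = "encoder_layer")
}

# One pre-norm block over a (B*T) x D batch matrix. Returns the output and,
# when want_cache, everything the backward pass needs. Dropout (training only)
# draws from the current RNG stream.
encoder_block_forward <- function(x, layer, B, T, training = FALSE,
                                  want_cache = FALSE) {
  h <- layer$heads; dh <- layer$head_dim
  scal <- 1 / sqrt(dh)
  ln1 <- layer_norm_forward(x, layer$ln1_g, layer$ln1_b)
  a <- ln1$y
  Q <- add_bias(a %*% layer$Wq, layer$bq)
  K <- add_bias(a %*% layer$Wk, layer$bk)
  V <- add_bias(a %*% layer$Wv, layer$bv)
  O <- matrix(0, nrow(x), h * dh)
  A_arr <- if (want_cache) array(0, dim = c(T, T, h, B)) else NULL
  drop_arr <- NULL
  p <- layer$attn_dropout
  use_drop <- training && p > 0
  if (use_drop && want_cache) drop_arr <- array(0, dim = c(T, T, h, B))
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    Qb <- Q[rows, , drop = FALSE]
    Kb <- K[rows, , drop = FALSE]
    Vb <- V[rows, , drop = FALSE]
    for (m in seq_len(h)) {
      cols <- ((m - 1L) * dh + 1L):(m * dh)
      S <- tcrossprod(Qb[, cols, drop = FALSE], Kb[, cols, drop = FALSE]) * scal
      A <- softmax_rows(S)
      if (use_drop) {
        mask <- matrix(stats::runif(T * T) >= p, T, T) / (1 - p)
        A_used <- A * mask
        if (want_cache) drop_arr[, , m, b] <- mask
      } else {
        A_used <- A
      }
      if (want_cache) A_arr[, , m, b] <- A
      O[rows, cols] <- A_used %*% Vb[, cols, drop = FALSE]
    }
  }
  attn_out <- add_bias(O %*% layer$Wo, layer$bo)
  x2 <- x + attn_out
  ln2 <- layer_norm_forward(x2, layer$ln2_g, layer$ln2_b)
  u <- add_bias(ln2$y %*% layer$W1, layer$b1)
  gu <- gelu(u)
  x3 <- x2 + add_bias(gu %*% layer$W2, layer$b2)
  cache <- NULL
  if (want_cache) {
    cache <- list(x = x, ln1 = ln1, a = a, Q = Q, K = K, V = V,
                  A = A_arr, drop = drop_arr, O = O, x2 = x2, ln2 = ln2,
                  u = u, gu = gu, B = B, T = T)
  }
  list(x = x3, cache = cache)
}

# Backward through one block. dx_out: gradient at block output.
# Returns dx at the block input plus a named list of parameter gradients.
encoder_block_backward <- function(dx_out, cache, layer) {
  h <- layer$heads; dh <- layer$head_dim
  B <- cache$B; T <- cache$T
  scal <- 1 / sqrt(dh)
  # MLP branch
  d_b2 <- colSums(dx_out)
  d_W2 <- crossprod(cache$gu, dx_out)
  dgu <- dx_out %*% t(layer$W2)
  du <- dgu * gelu_grad(cache$u)
  d_b1 <- colSums(du)
  d_W1 <- crossprod(cache$ln2$y, du)
  dm <- du %*% t(layer$W1)
  ln2b <- layer_norm_backward(dm, cache$ln2, layer$ln2_g)
  dx2 <- dx_out + ln2b$dx
  # attention branch
  d_bo <- colSums(dx2)
  d_Wo <- crossprod(cache$O, dx2)
  dO <- dx2 %*% t(layer$Wo)
  dQ <- matrix(0, nrow(dO), h * dh)
  dK <- matrix(0, nrow(dO), h * dh)
  dV <- matrix(0, nrow(dO), h * dh)
  p <- layer$attn_dropout
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    for (m in seq_len(h)) {
      cols <- ((m - 1L) * dh + 1L):(m * dh)
      A <- cache$A[, , m, b]
      mask <- if (!is.null(cache$drop)) cache$drop[, , m, b] else NULL
      A_used <- if (is.null(mask)) A else A * mask
      dOb <- dO[rows, cols, drop = FALSE]
      Vb <- cache$V[rows, cols, drop = FALSE]
      dA <- tcrossprod(dOb, Vb)
      dV[rows, cols] <- crossprod(A_used, dOb)
      if (!is.null(mask)) dA <- dA * mask
      dS <- A * (dA - rowSums(dA * A))
      Qb <- cache$Q[rows, cols, drop = FALSE]
      Kb <- cache$K[rows, cols, drop = FALSE]
      dQ[rows, cols] <- dS %*% Kb * scal
      dK[rows, cols] <- crossprod(dS, Qb) * scal
    }
  }
  d_bq <- colSums(dQ); d_bk <- colSums(dK); d_bv <- colSums(dV)
  a <- cache$a
  d_Wq <- crossprod(a, dQ)
  d_Wk <- crossprod(a, dK)
  d_Wv <- crossprod(a, dV)
  da <- dQ %*% t(layer$Wq) + dK %*% t(layer$Wk) + dV %*% t(layer$Wv)
  ln1b <- layer_norm_backward(da, cache$ln1, layer$ln1_g)
  dx <- dx2 + ln1b$dx
  list(dx = dx,
       grads = list(Wq = d_Wq, bq = d_bq, Wk = d_Wk, bk = d_bk,
                    Wv = d_Wv, bv = d_bv, Wo = d_Wo, bo = d_bo,
                    ln1_g = ln1b$dg, ln1_b = ln1b$db,
                    ln2_g = ln2b$dg, ln2_b = ln2b$db,
                    W1 = d_W1, b1 = d_b1, W2 = d_W2, b2 = d_b2))
}

#' Run a token sequence through a stack of encoder layers
#'
#' Applies pre-norm residual blocks in order. Dropout on the attention weights
#' is active only in training mode. The final layer normalisation applied
#' before the classification head is part of the model ([build_model()]), not
#' of this stack.
#'
#' @param tokens (N + 1) x D token matrix (class token at row 1 by
#'   convention, though the stack itself is agnostic).
#' @param layers List of [new_encoder_layer()] objects.
#' @param training_mode Logical; enables attention dropout.
#' @return Matrix of the same shape as `tokens`.
#' @export
encoder_forward <- function(tokens, layers, training_mode = FALSE) {
  x <- tokens
  for (layer in layers) {
    x <- encoder_block_forward(x, layer, B = 1L, T = nrow(tokens),
                               training = training_mode)$x
  }
  x
}

#' Create a binary classification head
#'
#' @param embed_dim Token dimension D.
#' @param num_classes Number of output classes (2: non-tumor, tumor).
#' @param sd Optional normal-init standard deviation; fan-in scaled uniform
#'   by default.
#' @return Object of class `classifier_head` with `W` (D x num_classes) and
#'   `b`.
#' @export
new_classifier_head <- function(embed_dim, num_classes = 2L, sd = NULL) {
  structure(list(W = init_weight(embed_dim, num_classes, sd),
                 b = numeric(num_classes)),
            class = "classifier_head")
}

#' Classify an encoded sequence from its class token
#'
#' Applies the linear head to the class-token row (row 1) and a softmax over
#' the two logits: `y = softmax(W' h_cls + b)`. Column/class order is
#' (non-tumor, tumor).
#'
#' @param encoded (N + 1) x D encoder output with the class token at row 1.
#' @param head A [new_classifier_head()] object.
#' @return Named numeric vector of 2 probabilities summing to 1.
#' @export
classify <- function(encoded, head) {
  logits <- drop(encoded[1L, , drop = FALSE] %*% head$W) + head$b
  e <- exp(logits - max(logits))
  p <- e / sum(e)
  names(p) <- c("negative", "positive")[seq_along(p)]
  p
}
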