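test_that("embed_patches is the affine map patches %*% E + b", {
  proj <- list(W = matrix(c(1, 3, 2, 4), 2, 2), b = c(0, 0))
  expect_equal(embed_patches(matrix(c(1, 0), 1, 2), proj),
               matrix(c(1, 2), 1, 2))
  # zero patches: every token equals the bias
  proj$b <- c(0.5, -0.25)
  z <- embed_patches(matrix(0, 3, 2), proj)
  expect_equal(z, matrix(rep(proj$b, each = 3), 3, 2))
  # random case against an explicit elementwise oracle
  withr::with_seed(10, {
    P <- matrix(rnorm(5 * 4), 5, 4)
    W <- matrix(rnorm(4 * 3), 4, 3)
    b <- rnorm(3)
  })
  oracle <- matrix(0, 5, 3)
  for (i in 1:5) for (d in 1:3) oracle[i, d] <- sum(P[i, ] * W[, d]) + b[d]
  expect_equal(embed_patches(P, list(W = W, b = b)), oracle)
})

test_that("embedding dimension mismatches are reported with both sizes", {
  proj <- list(W = matrix(0, 4, 3), b = numeric(3))
  expect_error(embed_patches(matrix(0, 2, 5), proj), "5.*4")
})

test_that("embed_patches is linear up to the bias term", {
  withr::with_seed(11, {
    proj <- new_patch_projector(6, 4)
    P <- matrix(rnorm(12), 2, 6)
    Q <- matrix(rnorm(12), 2, 6)
  })
  a <- 0.7; b <- -1.3
  lhs <- embed_patches(a * P + b * Q, proj)
  rhs <- a * embed_patches(P, proj) + b * embed_patches(Q, proj) -
    (a + b - 1) * matrix(rep(proj$b, each = 2), 2, 4)
  expect_equal(lhs, rhs)
})

test_that("rotation averaging is the elementwise mean", {
  z <- matrix(c(0.2), 1, 1)
  expect_identical(average_rotated_embeddings(list(z)), z)
  expect_equal(average_rotated_embeddings(list(z, matrix(0.4, 1, 1))),
               matrix(0.3, 1, 1))
  zz <- matrix(rnorm(12), 3, 4)
  expect_equal(average_rotated_embeddings(list(zz, zz, zz)), zz)
  expect_error(average_rotated_embeddings(list()), "non-empty")
  expect_error(average_rotated_embeddings(list(zz, matrix(0, 2, 2))), "shape")
})

test_that("class token and positions are prepended then added", {
  tok <- matrix(0, 2, 3)
  pos <- matrix(rnorm(9), 3, 3)
  expect_equal(add_class_and_positions(tok, numeric(3), pos), pos)
  tok2 <- matrix(rnorm(6), 2, 3)
  cls <- rnorm(3)
  out <- add_class_and_positions(tok2, cls, matrix(0, 3, 3))
  expect_equal(out, rbind(cls, tok2), ignore_attr = TRUE)
  # random case against concatenate-then-add oracle
  out2 <- add_class_and_positions(tok2, cls, pos)
  expect_equal(out2, rbind(cls, tok2) + pos, ignore_attr = TRUE)
  expect_error(add_class_and_positions(tok2, cls, matrix(0, 4, 3)),
               "4.*3")
})

test_that("identity-initialised stem is the identity map", {
  stem <- new_depthwise_stem(2L, init = "identity")
  img <- rand_image(8, channels = 2L, seed = 12)
  expect_equal(depthwise_stem(img, stem), as_image_array(img))
})

test_that("stem of a constant image is constant (shift invariance)", {
  withr::with_seed(13, stem <- new_depthwise_stem(1L))
  img <- matrix(0.4, 12, 12)
  out <- depthwise_stem(img, stem)
  inner <- out[3:10, 3:10, 1L]   # away from the zero-padded border
  expect_lt(diff(range(inner)), 1e-12)
})

test_that("stem matches a naive sliding-window convolution oracle", {
  withr::with_seed(14, stem <- new_depthwise_stem(1L, kernel_size = 3L))
  img <- rand_image(8, seed = 15)
  out <- depthwise_stem(img, stem)
  # naive cross-correlation with zero padding, then pointwise map
  oracle_mid <- matrix(0, 8, 8)
  for (y in 1:8) for (x in 1:8) {
    acc <- stem$dw_bias[1L]
    for (u in -1:1) for (v in -1:1) {
      yy <- y + u; xx <- x + v
      if (yy >= 1 && yy <= 8 && xx >= 1 && xx <= 8) {
        acc <- acc + stem$dw[u + 2L, v + 2L, 1L] * img[yy, xx]
      }
    }
    oracle_mid[y, x] <- acc
  }
  oracle <- oracle_mid * stem$pw[1L, 1L] + stem$pw_bias[1L]
  expect_equal(out[, , 1L], oracle)
})

test_that("averaged embeddings are exactly invariant to quarter rotations", {
  # full embedding map M(X) = mean_j embed(patches(stem(X^(j)))) built from
  # the public operations, with random weights
  withr::with_seed(16, {
    stem <- new_depthwise_stem(1L)
    proj <- new_patch_projector(4 * 4 * 1, 6)
    img <- rand_image(8, seed = 17)
  })
  embed_map <- function(x) {
    rs <- make_rotation_set(x, 4)
    zs <- lapply(rs$images, function(xi) {
      embed_patches(extract_patches(depthwise_stem(xi, stem), 4), proj)
    })
    average_rotated_embeddings(zs)
  }
  m0 <- embed_map(img)
  m1 <- embed_map(rotate_quarter(img, 1))
  expect_lt(max(abs(m1 - m0)), 1e-5)
  # averaging is idempotent on rotation-symmetric inputs
  const <- matrix(0.3, 8, 8)
  z_const <- embed_patches(extract_patches(depthwise_stem(const, stem), 4),
                           proj)
  expect_equal(embed_map(const), z_const)
})
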