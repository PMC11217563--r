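test_that("quarter rotation follows the counter-clockwise convention", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)      # rows (1,2) / (3,4)
  expect_identical(rotate_quarter(m, 0), m)
  expect_identical(rotate_quarter(m, 1), matrix(c(2, 1, 4, 3), 2, 2))
  expect_identical(rotate_quarter(m, 5), rotate_quarter(m, 1))
  expect_identical(rotate_quarter(m, -1), rotate_quarter(m, 3))
})

test_that("rotation is an exact pixel permutation with period four", {
  img <- rand_image(8, channels = 2L, seed = 1)
  x <- img
  for (i in 1:4) x <- rotate_quarter(x, 1)
  expect_identical(x, img)                       # bit-exact group closure
  r1 <- rotate_quarter(img, 1)
  expect_identical(sort(as.vector(r1)), sort(as.vector(img)))
  expect_identical(rotate_quarter(rotate_quarter(img, 1), 1),
                   rotate_quarter(img, 2))
})

test_that("non-square images are rejected for rotation", {
  expect_error(rotate_quarter(matrix(0, 2, 3), 1), "square")
})

test_that("make_rotation_set enumerates equally spaced quarter turns", {
  img <- rand_image(8, seed = 2)
  expect_error(make_rotation_set(img, 3), "1, 2, 4")
  s1 <- make_rotation_set(img, 1)
  expect_length(s1$images, 1L)
  expect_identical(s1$images[[1L]], img)
  s2 <- make_rotation_set(img, 2)
  expect_identical(s2$quarter_turns, c(0L, 2L))
  const <- matrix(0.5, 8, 8)
  s4 <- make_rotation_set(const, 4)
  for (j in 2:4) expect_identical(s4$images[[j]], s4$images[[1L]])
})

test_that("rotating the source cyclically shifts its rotation set", {
  img <- rand_image(8, seed = 3)
  s0 <- make_rotation_set(img, 4)
  s1 <- make_rotation_set(rotate_quarter(img, 1), 4)
  # element j of s1 is rot^(j+1) of img: s1 = s0 shifted by one position
  for (j in 1:4) {
    expect_identical(s1$images[[j]], s0$images[[(j %% 4) + 1L]])
  }
})

test_that("patch extraction follows row-major grid and pixel order", {
  img <- matrix(as.numeric(1:16), 4, 4, byrow = TRUE)  # img[y, x] = 4(y-1)+x
  p <- extract_patches(img, 2)
  expect_identical(dim(p), c(4L, 4L))
  expect_identical(p[1L, ], c(1, 2, 5, 6))    # top-left block, row-major
  expect_identical(p[2L, ], c(3, 4, 7, 8))    # scan left-to-right first
  expect_identical(p[3L, ], c(9, 10, 13, 14))
  # channel-last layout: channels of one pixel are adjacent
  img2 <- array(c(1, 0, 0, 0, 2, 0, 0, 0), dim = c(2, 2, 2))
  p2 <- extract_patches(img2, 2)
  expect_identical(p2[1L, 1:2], c(1, 2))
})

test_that("patch counts and lengths match the grid arithmetic", {
  img <- rand_image(224, channels = 3L, seed = 4)
  p <- extract_patches(img, 16)
  expect_identical(dim(p), c(196L, 768L))
  expect_error(extract_patches(rand_image(10), 3), "10 x 10.*3")
})

test_that("reassembly inverts extraction on any divisible geometry", {
  for (geom in list(c(8, 2, 1), c(12, 4, 3), c(6, 3, 2))) {
    img <- rand_image(geom[1], channels = geom[3], seed = geom[1])
    img <- as_image_array(img)
    p <- extract_patches(img, geom[2])
    back <- reassemble_patches(p, geom[1], geom[1], geom[3])
    expect_identical(back, img)
  }
})

test_that("rotating the image permutes and rotates its patches", {
  # brute force on an 8x8 image with 2x2 patches: patch (r, c) of the rotated
  # image equals the quarter-rotated patch (c, g - 1 - r) of the original
  img <- rand_image(8, seed = 5)
  g <- 4L
  p0 <- extract_patches(img, 2)
  p1 <- extract_patches(rotate_quarter(img, 1), 2)
  as_block <- function(row) matrix(row, 2, 2, byrow = TRUE)
  for (r in 0:(g - 1L)) {
    for (c in 0:(g - 1L)) {
      got <- as_block(p1[r * g + c + 1L, ])
      src <- as_block(p0[c * g + (g - 1L - r) + 1L, ])
      expect_identical(got, rotate_quarter(src, 1))
    }
  }
})
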