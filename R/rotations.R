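# Lossless quarter-turn rotations and image <-> patch decomposition.
#
# Images are H x W x C arrays (or plain H x W matrices) with intensities in
# [0, 1]; the first index is the image row (y, top to bottom), the second the
# column (x, left to right). All rotations are exact pixel permutations.

#' Coerce an image to a 3-D H x W x C array
#'
#' Plain matrices are treated as single-channel images. Used internally so all
#' pipeline stages can assume a channel axis.
#'
#' @param image A numeric matrix (H x W) or array (H x W x C).
#' @return An H x W x C numeric array.
#' @keywords internal
as_image_array <- function(image) {
  if (is.matrix(image)) {
    array(image, dim = c(dim(image), 1L))
  } else if (is.array(image) && length(dim(image)) == 3L) {
    image
  } else {
    stop("image must be an H x W matrix or an H x W x C array", call. = FALSE)
  }
}

# Counter-clockwise quarter turns of a matrix, q in {0,1,2,3}.
rotate2d <- function(m, q) {
  switch(q + 1L,
    m,
    t(m)[rev(seq_len(ncol(m))), , drop = FALSE],
    m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE],
    t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  )
}

#' Rotate a square image by quarter turns
#'
#' Rotates a square image counter-clockwise by `quarter_turns` * 90 degrees.
#' The rotation is an exact permutation of pixels: no interpolation takes
#' place and applying it four times returns the input bit-exactly.
#'
#' @param image Square numeric matrix (H x H) or array (H x H x C).
#' @param quarter_turns Integer number of counter-clockwise quarter turns;
#'   any integer is accepted and taken modulo 4.
#' @return The rotated image, with the same dimensions and storage shape
#'   (matrix in, matrix out).
#' @examples
#' m <- matrix(c(1, 3, 2, 4), 2, 2) # rows: (1,2), (3,4)
#' rotate_quarter(m, 1)             # rows: (2,4), (1,3)
#' @export
rotate_quarter <- function(image, quarter_turns) {
  was_matrix <- is.matrix(image)
  img <- as_image_array(image)
  d <- dim(img)
  if (d[1L] != d[2L]) {
    stop(sprintf("rotation requires a square image; got %d x %d", d[1L], d[2L]),
         call. = FALSE)
  }
  q <- as.integer(quarter_turns) %% 4L
  if (q != 0L) {
    out <- array(0, dim = d)
    for (c in seq_len(d[3L])) out[, , c] <- rotate2d(img[, , c], q)
    img <- out
  }
  if (was_matrix) img[, , 1L] else img
}

#' Generate the set of quarter-rotated copies of an image
#'
#' Returns the `k` rotated versions of a square image used by the
#' rotation-averaged patch embedding: element `j` (1-based index `j + 1`) is
#' the image rotated counter-clockwise by `j * (4 / k)` quarter turns, so the
#' angles are equally spaced over the 4-fold rotation group and element 1 is
#' always the unrotated input.
#'
#' @param image Square numeric matrix or H x H x C array.
#' @param k Number of rotations; one of 1, 2 or 4 (divisors of the 4-fold
#'   group, so the set is closed under further quarter turns).
#' @return An object of class `rotation_set`: a list with `images` (list of
#'   `k` arrays) and `quarter_turns` (integer vector of the turns applied).
#' @export
make_rotation_set <- function(image, k = 4L) {
  k <- as.integer(k)
  if (!k %in% c(1L, 2L, 4L)) {
    stop(sprintf("k must be one of 1, 2, 4 (got %d)", k), call. = FALSE)
  }
  step <- 4L %/% k
  turns <- (seq_len(k) - 1L) * step
  images <- lapply(turns, function(q) rotate_quarter(image, q))
  structure(list(images = images, quarter_turns = turns),
            class = "rotation_set")
}

# Linear-index map from an H x W x C array (column-major) to an
# N x (P^2 * C) patch matrix. Row i is grid patch i in row-major order
# (top-left first, scanning left-to-right then top-to-bottom); within a patch
# the flat order is row-major over pixels with channels fastest
# (channel-last layout). Memoised per geometry: extraction is on the
# training hot path.
.patch_map_cache <- new.env(parent = emptyenv())

patch_index_map <- function(H, W, C, P) {
  key <- paste(H, W, C, P, sep = "_")
  if (!is.null(.patch_map_cache[[key]])) return(.patch_map_cache[[key]])
  gh <- H %/% P
  gw <- W %/% P
  # within-patch offsets, channel fastest, then px, then py
  cvec <- rep(0:(C - 1L), times = P * P)
  pxv <- rep(rep(0:(P - 1L), each = C), times = P)
  pyv <- rep(0:(P - 1L), each = C * P)
  # patch origins, row-major over the grid
  grv <- rep(0:(gh - 1L), each = gw)
  gcv <- rep(0:(gw - 1L), times = gh)
  A <- gcv * P * H + grv * P              # per-patch origin offset
  B <- cvec * H * W + pxv * H + pyv + 1L  # per-element offset within patch
  M <- outer(A, B, "+")
  .patch_map_cache[[key]] <- M
  M
}

#' Decompose an image into a sequence of flattened patches
#'
#' Splits an H x W x C image into non-overlapping `patch_size` x `patch_size`
#' blocks and flattens each into a row vector of length `patch_size^2 * C`.
#' Patches are ordered row-major over the grid (top-left patch first, scanning
#' left-to-right then top-to-bottom); within each patch, pixels are row-major
#' with channels last (adjacent channels of a pixel are contiguous).
#'
#' @param image Numeric matrix or H x W x C array; both `H` and `W` must be
#'   divisible by `patch_size`.
#' @param patch_size Patch side length in pixels.
#' @return An N x (patch_size^2 * C) numeric matrix, N = (H/P) * (W/P), with
#'   attributes `patch_size`, `grid` (c(H/P, W/P)) and `channels`.
#' @export
extract_patches <- function(image, patch_size) {
  img <- as_image_array(image)
  d <- dim(img)
  P <- as.integer(patch_size)
  if (d[1L] %% P != 0L || d[2L] %% P != 0L) {
    stop(sprintf("image size %d x %d is not divisible by patch size %d",
                 d[1L], d[2L], P), call. = FALSE)
  }
  M <- patch_index_map(d[1L], d[2L], d[3L], P)
  patches <- matrix(img[as.vector(M)], nrow = nrow(M))
  attr(patches, "patch_size") <- P
  attr(patches, "grid") <- c(d[1L] %/% P, d[2L] %/% P)
  attr(patches, "channels") <- d[3L]
  patches
}

#' Reassemble an image from its patch sequence
#'
#' Exact inverse of [extract_patches()] given the original geometry.
#'
#' @param patches N x (P^2 * C) patch matrix as returned by
#'   [extract_patches()].
#' @param height,width,channels Original image dimensions.
#' @param patch_size Patch side length used for extraction; defaults to the
#'   `patch_size` attribute of `patches`.
#' @return An H x W x C numeric array.
#' @export
reassemble_patches <- function(patches, height, width, channels = 1L,
                               patch_size = attr(patches, "patch_size")) {
  M <- patch_index_map(height, width, channels, as.integer(patch_size))
  stopifnot(all(dim(M) == dim(patches)))
  img <- array(0, dim = c(height, width, channels))
  img[as.vector(M)] <- as.vector(patches)
  img
}
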