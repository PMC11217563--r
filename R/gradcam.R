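# Grad-CAM over the patch-token grid. Token embedding dimensions play the
# role of channels; the token grid plays the role of spatial locations.
# Activations and gradients are taken at the INPUT of the last encoder layer:
# only the class token feeds the head, so the gradient of the logit with
# respect to the last layer's *output* non-class tokens is identically zero,
# whereas at the layer input the class token still attends to every patch
# token.
#
# The per-token score is the rectified inner product <grad_i, act_i> — the
# first-order (Taylor) contribution of token i to the target logit. In CNN
# Grad-CAM the gradient is average-pooled over spatial positions because a
# channel carries one semantic across the map; transformer tokens carry a
# large shared residual-stream component across positions, which dominates a
# pooled-weight projection and washes out localisation, so the attribution is
# kept per token.

# Saliency for one (possibly rotated) input, attributed through the j = 0
# branch of the model.
gradcam_core <- function(model, image, target_class) {
  cfg <- model$config
  fw <- model_forward(model, list(image), training = FALSE, want_cache = TRUE)
  dlogits <- matrix(0, 1L, cfg$num_classes)
  dlogits[1L, target_class + 1L] <- 1
  bw <- model_backward(model, fw$cache, dlogits)
  act <- bw$last_input_act[-1L, , drop = FALSE]   # non-class tokens
  grad <- bw$last_input_grad[-1L, , drop = FALSE]
  cam <- pmax(0, rowSums(grad * act))
  g <- cfg$image_size %/% cfg$patch_size
  matrix(cam, g, g, byrow = TRUE)                  # row-major patch order
}

normalize01 <- function(m) {
  mx <- max(m)
  if (mx > 0) m / mx else m
}

#' Grad-CAM saliency map for one image
#'
#' Computes the gradient of the target-class logit with respect to the token
#' activations entering the last encoder layer, scores each patch token by
#' the rectified inner product of its gradient and activation (its
#' first-order contribution to the logit), reshapes the scores to the patch
#' grid, normalises to \[0, 1\] and bilinearly upsamples to the image size.
#'
#' With `branch = "unrotated"` (default) the attribution flows through the
#' j = 0 rotation branch only. With `branch = "averaged"` the map is the
#' average of the per-branch maps, each computed in its branch's own frame and
#' rotated back. For a rotation-averaged model the logit being explained is
#' identical across the four rotations of the input, but the unrotated-branch
#' map itself need not be.
#'
#' @param model A trained `rvit_model` (evaluation mode is used).
#' @param image Square image (matrix or H x W x C array) at the model's input
#'   size.
#' @param target_class 0 (non-tumor) or 1 (tumor).
#' @param branch `"unrotated"` or `"averaged"`.
#' @return Object of class `saliency_map`: list with `grid`
#'   ((H/P) x (W/P), in \[0, 1\]), `upsampled` (H x W, in \[0, 1\]),
#'   `target_class` and `branch`.
#' @export
gradcam <- function(model, image, target_class = 1L,
                    branch = c("unrotated", "averaged")) {
  branch <- match.arg(branch)
  stopifnot(inherits(model, "rvit_model"), target_class %in% c(0L, 1L))
  cfg <- model$config
  if (branch == "unrotated") {
    grid <- gradcam_core(model, image, target_class)
  } else {
    k <- effective_k(cfg)
    step <- 4L %/% k
    maps <- lapply(0:(k - 1L), function(j) {
      m <- gradcam_core(model, rotate_quarter(image, j * step), target_class)
      rotate_quarter(m, -j * step)                 # back to the input frame
    })
    grid <- Reduce(`+`, maps) / k
  }
  grid <- normalize01(grid)
  H <- cfg$image_size
  up <- as.matrix(EBImage::resize(grid, w = H, h = H))
  up[up < 0] <- 0
  up <- normalize01(up)
  structure(list(grid = grid, upsampled = up,
                 target_class = as.integer(target_class), branch = branch),
            class = "saliency_map")
}

#' Write a Grad-CAM overlay PNG
#'
#' Alpha-blends a heat colormap of the saliency map onto the (grayscale)
#' input image; blending weight at each pixel is `alpha * saliency`, so
#' low-saliency regions show the underlying anatomy.
#'
#' @param map A [gradcam()] result.
#' @param image The input image the map was computed from.
#' @param path Output PNG path.
#' @param alpha Maximum blend weight in \[0, 1\].
#' @return `path`, invisibly.
#' @export
write_gradcam_overlay <- function(map, image, path, alpha = 0.6) {
  stopifnot(inherits(map, "saliency_map"))
  img <- as_image_array(image)
  gray <- if (dim(img)[3L] == 1L) img[, , 1L] else
    apply(img, c(1L, 2L), mean)
  sal <- map$upsampled
  ramp <- grDevices::colorRamp(c("navy", "cyan", "yellow", "red"))
  cols <- ramp(as.vector(sal)) / 255
  H <- nrow(sal); W <- ncol(sal)
  w <- alpha * as.vector(sal)
  out <- array(0, dim = c(H, W, 3L))
  for (c in 1:3) {
    out[, , c] <- matrix((1 - w) * as.vector(gray) + w * cols[, c], H, W)
  }
  out[out < 0] <- 0; out[out > 1] <- 1
  png::writePNG(out, path)
  invisible(path)
}
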