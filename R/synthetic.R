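# Synthetic MRI-like phantoms: a bright "brain" disk with low-frequency
# texture and Gaussian noise, plus (for positives) one bright elliptical
# lesion of controlled size and orientation. Ground-truth lesion masks are
# retained so saliency maps can be checked for localisation. The generator is
# a pure function of (spec, seed).

#' Phantom generator specification
#'
#' @param image_size Side length in pixels.
#' @param n_images Number of images for [generate_dataset()].
#' @param tumor_fraction Fraction of positive (lesion) images in (0, 1).
#' @param lesion_axes Range (min, max) of the lesion semi-major axis, pixels;
#'   defaults to `image_size * c(0.17, 0.23)` (11-15 px at 64).
#' @param lesion_aspect Ratio of semi-major to semi-minor axis (>= 1);
#'   elongated lesions make orientation matter.
#' @param lesion_intensity Peak intensity lift added at the lesion centre.
#' @param texture_scale Amplitude of the low-frequency background texture.
#' @param noise_sd Standard deviation of the per-pixel Gaussian noise.
#' @param distractor_count Range (min, max) of bright circular "anatomical"
#'   bumps added to EVERY image (both classes). They make plain local
#'   brightness only partially informative, so classifiers must also use the
#'   lesion's elongated shape.
#' @param distractor_radius Range of distractor bump radii, pixels; defaults
#'   to `image_size * c(0.0625, 0.11)` (4-7 px at 64).
#' @param distractor_intensity Peak lift of the distractor bumps; defaults to
#'   0.7 * `lesion_intensity`.
#' @param orientation_range Lesion orientation range in degrees
#'   (e.g. `c(0, 360)` for uniform, `c(-15, 15)` for horizontally biased).
#' @param seed Integer seed; together with the spec it fully determines the
#'   dataset.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 64L, n_images = 500L,
                         tumor_fraction = 0.5,
                         lesion_axes = NULL, lesion_aspect = 2.5,
                         lesion_intensity = 0.60,
                         texture_scale = 0.03, noise_sd = 0.02,
                         distractor_count = c(1L, 3L),
                         distractor_radius = NULL,
                         distractor_intensity = 0.42 * lesion_intensity,
                         orientation_range = c(0, 360),
                         seed = 1L) {
  if (is.null(lesion_axes)) lesion_axes <- image_size * c(0.17, 0.23)
  if (is.null(distractor_radius)) {
    distractor_radius <- image_size * c(0.0625, 0.11)
  }
  stopifnot(tumor_fraction > 0, tumor_fraction < 1,
            length(lesion_axes) == 2L, lesion_axes[1] <= lesion_axes[2],
            lesion_aspect >= 1, lesion_intensity >= 0, noise_sd >= 0,
            length(orientation_range) == 2L, length(distractor_count) == 2L,
            length(distractor_radius) == 2L, distractor_intensity >= 0)
  spec <- list(image_size = as.integer(image_size),
               n_images = as.integer(n_images),
               tumor_fraction = tumor_fraction,
               lesion_axes = as.numeric(lesion_axes),
               lesion_aspect = lesion_aspect,
               lesion_intensity = lesion_intensity,
               texture_scale = texture_scale, noise_sd = noise_sd,
               distractor_count = as.integer(distractor_count),
               distractor_radius = as.numeric(distractor_radius),
               distractor_intensity = distractor_intensity,
               orientation_range = as.numeric(orientation_range),
               seed = as.integer(seed))
  disk_radius <- 0.42 * spec$image_size
  if (spec$lesion_axes[2] >= disk_radius) {
    stop(sprintf(
      "lesion semi-major axis (up to %.1f px) exceeds the brain disk radius (%.1f px)",
      spec$lesion_axes[2], disk_radius), call. = FALSE)
  }
  structure(spec, class = "phantom_spec")
}

#' Generate one phantom image
#'
#' Builds a smooth bright disk (the simulated brain) on a dark background,
#' adds low-frequency cosine texture inside the disk and Gaussian pixel noise,
#' and, for `label = 1`, one bright ellipse at a random centre, orientation
#' (within `spec$orientation_range`) and size (within `spec$lesion_axes`).
#' The lesion has compact support: outside its ellipse the image is identical
#' to the matched `label = 0` phantom generated from the same seed, because
#' the random draws occur in a fixed order regardless of the label. Intensities
#' are clipped to \[0, 1\].
#'
#' @param spec A [phantom_spec()].
#' @param label 0 (no lesion) or 1 (lesion).
#' @param seed Integer seed for this image.
#' @return H x W x 1 array with attributes `mask` (logical H x W lesion
#'   support, all-FALSE for label 0) and `lesion` (named list of the sampled
#'   lesion parameters).
#' @export
generate_phantom <- function(spec, label, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"), label %in% c(0L, 1L))
  s <- spec$image_size
  withr::with_seed(as.integer(seed), {
    ctr <- (s - 1) / 2
    yy <- matrix(0:(s - 1), s, s) - ctr          # row (y) coordinate
    xx <- matrix(0:(s - 1), s, s, byrow = TRUE) - ctr
    r <- sqrt(yy^2 + xx^2)
    r0 <- 0.42 * s
    edge <- 1 / (1 + exp((r - r0) / 1.5))        # soft disk mask
    img <- 0.08 + 0.55 * edge
    # low-frequency texture inside the disk (3 oriented cosine waves)
    for (w in 1:3) {
      amp <- spec$texture_scale * stats::runif(1, 0.5, 1)
      freq <- stats::runif(1, 0.5, 2.5)
      ang <- stats::runif(1, 0, 2 * pi)
      phase <- stats::runif(1, 0, 2 * pi)
      wave <- amp * cos(2 * pi * freq * (xx * cos(ang) + yy * sin(ang)) / s +
                          phase)
      img <- img + wave * edge
    }
    # circular distractor bumps in BOTH classes: local brightness alone is
    # then only partially informative and the lesion's elongation matters
    n_bump <- sample(spec$distractor_count[1]:spec$distractor_count[2], 1)
    for (d in seq_len(n_bump)) {
      rad <- stats::runif(1, spec$distractor_radius[1],
                          spec$distractor_radius[2])
      bpsi <- stats::runif(1, 0, 2 * pi)
      brho <- stats::runif(1, 0, max(r0 - rad - 2, 0))
      bx <- brho * cos(bpsi); by <- brho * sin(bpsi)
      bre2 <- ((xx - bx)^2 + (yy - by)^2) / rad^2
      img <- img + spec$distractor_intensity * pmax(0, 1 - bre2)
    }
    # lesion parameters are always drawn so the RNG stream is identical for
    # matched label-0 / label-1 phantoms
    theta <- stats::runif(1, spec$orientation_range[1],
                          spec$orientation_range[2]) * pi / 180
    a <- stats::runif(1, spec$lesion_axes[1], spec$lesion_axes[2])
    b <- a / spec$lesion_aspect
    psi <- stats::runif(1, 0, 2 * pi)
    rho <- stats::runif(1, 0, max(r0 - a - 2, 0))
    cx <- rho * cos(psi)
    cy <- rho * sin(psi)
    mask <- matrix(FALSE, s, s)
    if (label == 1L) {
      u <- (xx - cx) * cos(theta) + (yy - cy) * sin(theta)
      v <- -(xx - cx) * sin(theta) + (yy - cy) * cos(theta)
      re2 <- (u / a)^2 + (v / b)^2
      img <- img + spec$lesion_intensity * pmax(0, 1 - re2)
      mask <- re2 <= 1
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(s * s, 0, spec$noise_sd), s, s)
    }
    img[img < 0] <- 0
    img[img > 1] <- 1
    out <- array(img, dim = c(s, s, 1L))
    attr(out, "mask") <- mask
    attr(out, "lesion") <- list(cx = cx + ctr, cy = cy + ctr, a = a, b = b,
                                theta_deg = theta * 180 / pi)
    out
  })
}

#' Generate a labelled phantom dataset
#'
#' `round(tumor_fraction * n_images)` positives, label order shuffled by the
#' spec seed; each image gets its own derived seed, so the whole dataset is a
#' pure function of the spec. Ground-truth lesion masks are retained for the
#' Grad-CAM localisation checks.
#'
#' @param spec A [phantom_spec()].
#' @return An `rvit_dataset` with `images`, `labels`, `masks` (lesion support,
#'   NULL entries for negatives), `manifest` (data.frame of lesion
#'   parameters), and `classes = c(normal = 0, lesion = 1)`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_images
  n_pos <- round(spec$tumor_fraction * n)
  out <- withr::with_seed(spec$seed, {
    labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    list(labels = labels, seeds = seeds)
  })
  images <- vector("list", n)
  masks <- vector("list", n)
  man <- vector("list", n)
  for (i in seq_len(n)) {
    img <- generate_phantom(spec, out$labels[i], seed = out$seeds[i])
    masks[[i]] <- if (out$labels[i] == 1L) attr(img, "mask") else NULL
    les <- attr(img, "lesion")
    man[[i]] <- data.frame(index = i, label = out$labels[i],
                           cx = les$cx, cy = les$cy, a = les$a, b = les$b,
                           theta_deg = les$theta_deg, seed = out$seeds[i])
    attributes(img) <- list(dim = dim(img))
    images[[i]] <- img
  }
  structure(list(images = images, labels = out$labels, files = NULL,
                 classes = c(normal = 0L, lesion = 1L),
                 image_size = spec$image_size,
                 masks = masks, manifest = do.call(rbind, man),
                 spec = spec),
            class = "rvit_dataset")
}

#' Write a phantom dataset as an image folder
#'
#' Writes PNG files into the directory-per-class layout consumed by
#' [load_image_folder()] (`lesion/` and `normal/`), plus a `manifest.csv`
#' with filename, label and lesion parameters.
#'
#' @param dataset A dataset from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_folder <- function(dataset, dir) {
  stopifnot(inherits(dataset, "rvit_dataset"))
  dir.create(file.path(dir, "lesion"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "normal"), recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$images)
  fns <- character(n)
  for (i in seq_len(n)) {
    cl <- if (dataset$labels[i] == 1L) "lesion" else "normal"
    fn <- file.path(dir, cl, sprintf("img_%04d.png", i))
    png::writePNG(dataset$images[[i]][, , 1L], fn)
    fns[i] <- fn
  }
  man <- dataset$manifest
  man$filename <- fns
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Accuracy under the four quarter-turn rotations
#'
#' Evaluates the model on the dataset rotated by 0, 90, 180 and 270 degrees
#' and reports the four accuracies, their range, and the per-image predicted
#' labels at each angle (a rotation-invariant model gives identical
#' predictions, not merely equal accuracy).
#'
#' @param model A trained `rvit_model`.
#' @param dataset An `rvit_dataset`.
#' @param batch_size Images per forward batch.
#' @return Object of class `rotation_benchmark`: list with `table`
#'   (data.frame angle/accuracy), `range` (max - min accuracy) and
#'   `predictions` (n x 4 integer matrix).
#' @export
rotation_benchmark <- function(model, dataset, batch_size = 32L) {
  stopifnot(inherits(model, "rvit_model"), inherits(dataset, "rvit_dataset"))
  n <- length(dataset$images)
  preds <- matrix(0L, n, 4L)
  for (q in 0:3) {
    imgs <- lapply(dataset$images, rotate_quarter, quarter_turns = q)
    ds_q <- dataset
    ds_q$images <- imgs
    preds[, q + 1L] <- predict(model, ds_q, type = "class",
                               batch_size = batch_size)
  }
  acc <- colMeans(preds == dataset$labels)
  tab <- data.frame(angle = c(0L, 90L, 180L, 270L), accuracy = acc)
  structure(list(table = tab, range = max(acc) - min(acc),
                 predictions = preds),
            class = "rotation_benchmark")
}

#' @export
print.rotation_benchmark <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("accuracy range across angles: %g\n", x$range))
  invisible(x)
}
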