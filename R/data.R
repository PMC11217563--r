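# Dataset handling: directory-per-class image folders, stratified splitting.

#' Load a directory-per-class image dataset
#'
#' Reads a folder whose immediate subdirectories are the two classes (e.g.
#' `glioma/` and `notumor/` in the brain-MRI layout, or `lesion/` and
#' `normal/` from [write_phantom_folder()]). Images (PNG/JPEG/TIFF) are
#' decoded, resized to `image_size` x `image_size` (bilinear; aspect ratio is
#' not preserved) and scaled to \[0, 1\]. Files are ordered lexicographically
#' within each class, so loading is deterministic. Unreadable files are
#' skipped with a warning; an empty class directory is an error.
#'
#' @param root Dataset directory.
#' @param image_size Target side length in pixels.
#' @param positive_class Name of the subdirectory holding the positive
#'   (tumor) class. Default: the class whose lower-cased name is one of
#'   "glioma", "tumor", "lesion", "positive", "1"; otherwise the first class
#'   in sorted order, with a warning.
#' @param grayscale If `TRUE` (default) colour images are converted to
#'   luminance and stored as H x W x 1 arrays; otherwise channels are kept.
#' @return Object of class `rvit_dataset`: list with `images` (list of
#'   arrays), `labels` (integer 0/1; 1 = positive), `files`, `classes`
#'   (named vector mapping class name to label) and `image_size`.
#' @export
load_image_folder <- function(root, image_size = 224L, positive_class = NULL,
                              grayscale = TRUE) {
  if (!dir.exists(root)) stop(sprintf("no such directory: %s", root),
                              call. = FALSE)
  classes <- sort(basename(list.dirs(root, recursive = FALSE)))
  if (length(classes) != 2L) {
    stop(sprintf("expected exactly 2 class subdirectories under %s; found %d",
                 root, length(classes)), call. = FALSE)
  }
  if (is.null(positive_class)) {
    hit <- classes[tolower(classes) %in%
                     c("glioma", "tumor", "lesion", "positive", "1")]
    if (length(hit) == 1L) {
      positive_class <- hit
    } else {
      positive_class <- classes[1L]
      warning(sprintf(
        "could not infer the positive class; using '%s'. Pass positive_class=.",
        positive_class), call. = FALSE)
    }
  }
  if (!positive_class %in% classes) {
    stop(sprintf("positive_class '%s' is not a class directory",
                 positive_class), call. = FALSE)
  }
  images <- list(); labels <- integer(); files <- character()
  for (cl in classes) {
    fns <- sort(list.files(file.path(root, cl), full.names = TRUE,
                           pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                           ignore.case = TRUE))
    if (length(fns) == 0L) {
      stop(sprintf("class directory '%s' contains no images", cl),
           call. = FALSE)
    }
    lab <- as.integer(cl == positive_class)
    for (fn in fns) {
      img <- tryCatch(read_image_file(fn, image_size, grayscale),
                      error = function(e) {
                        warning(sprintf("skipping unreadable file %s: %s",
                                        fn, conditionMessage(e)),
                                call. = FALSE)
                        NULL
                      })
      if (is.null(img)) next
      images[[length(images) + 1L]] <- img
      labels <- c(labels, lab)
      files <- c(files, fn)
    }
  }
  class_map <- stats::setNames(as.integer(classes == positive_class), classes)
  structure(list(images = images, labels = labels, files = files,
                 classes = class_map, image_size = as.integer(image_size)),
            class = "rvit_dataset")
}

# Decode one image file to an H x W x C array in [0,1], resized to a square.
read_image_file <- function(path, image_size, grayscale = TRUE) {
  img <- EBImage::readImage(path)
  if (EBImage::colorMode(img) == EBImage::Color && grayscale) {
    img <- EBImage::channel(img, "luminance")
  }
  img <- EBImage::resize(img, w = image_size, h = image_size)
  a <- as.array(img)
  # EBImage stores (x, y[, c]); convert to row-major (y, x[, c])
  if (length(dim(a)) == 2L) {
    a <- array(t(a), dim = c(image_size, image_size, 1L))
  } else {
    a <- aperm(a, c(2L, 1L, 3L))
    if (dim(a)[3L] == 4L) a <- a[, , 1:3, drop = FALSE] # drop alpha
    if (grayscale && dim(a)[3L] > 1L) {
      a <- array(rowMeans(matrix(a, ncol = dim(a)[3L])),
                 dim = c(image_size, image_size, 1L))
    }
  }
  a[a < 0] <- 0; a[a > 1] <- 1
  a
}

# Subset a dataset, keeping any masks/manifest columns aligned.
dataset_subset <- function(ds, idx) {
  out <- ds
  out$images <- ds$images[idx]
  out$labels <- ds$labels[idx]
  if (!is.null(ds$files)) out$files <- ds$files[idx]
  if (!is.null(ds$masks)) out$masks <- ds$masks[idx]
  if (!is.null(ds$manifest)) out$manifest <- ds$manifest[idx, , drop = FALSE]
  out
}

#' Number of items in a dataset
#' @param x An `rvit_dataset`.
#' @export
length.rvit_dataset <- function(x) length(x$images)

#' Stratified train/validation split
#'
#' Splits a dataset into train and validation parts, stratified by class:
#' within each class, `floor(fraction * n_class)` items go to the training
#' set after a seeded permutation. The two parts are disjoint and exhaustive,
#' and the split is reproducible from the seed.
#'
#' @param dataset An `rvit_dataset`.
#' @param fraction Training fraction in (0, 1); default 0.8.
#' @param seed Integer seed for the permutation.
#' @return List with elements `train` and `val` (both `rvit_dataset`).
#' @export
split_train_val <- function(dataset, fraction = 0.8, seed = 1L) {
  stopifnot(inherits(dataset, "rvit_dataset"))
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  labs <- dataset$labels
  tr_idx <- integer()
  for (cl in sort(unique(labs))) {
    idx <- which(labs == cl)
    if (length(idx) < 2L) {
      stop(sprintf("class %d has fewer than 2 items; cannot split", cl),
           call. = FALSE)
    }
    perm <- withr::with_seed(as.integer(seed) + cl,
                             sample(length(idx)))
    n_tr <- floor(fraction * length(idx))
    tr_idx <- c(tr_idx, idx[perm[seq_len(n_tr)]])
  }
  tr_idx <- sort(tr_idx)
  va_idx <- setdiff(seq_along(labs), tr_idx)
  list(train = dataset_subset(dataset, tr_idx),
       val = dataset_subset(dataset, va_idx))
}
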