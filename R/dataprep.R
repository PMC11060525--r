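# Dataset normalization, splitting, balancing and train-time augmentation.

#' Largest-remainder apportionment of n items to fractions
#'
#' Each split receives `floor(n * fraction)` items; the leftover items go to
#' the splits with the largest fractional remainders. This is the rounding
#' rule under which 16,331 items at 75/15/10 yield 12,248 / 2,450 / 1,633.
#'
#' @param n Total number of items.
#' @param fractions Named numeric vector summing to 1.
#' @return Named integer vector summing to `n`.
#' @export
#' @examples
#' split_sizes(16331, c(train = 0.75, test = 0.15, validation = 0.10))
split_sizes <- function(n, fractions = c(train = 0.75, test = 0.15,
                                         validation = 0.10)) {
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  if (any(fractions <= 0) || any(fractions >= 1)) {
    stop("each fraction must lie in (0, 1)", call. = FALSE)
  }
  quota <- n * fractions
  sizes <- floor(quota)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(quota - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  stats::setNames(as.integer(sizes), names(fractions))
}

#' Split an image set into train / test / validation
#'
#' Random, disjoint, exhaustive partition. With `stratify = TRUE` (the
#' default) the largest-remainder rule is applied within each class, which
#' protects sparsely populated classes; global split sizes may then differ
#' from [split_sizes()] of the total by at most one item per class. With
#' `stratify = FALSE` the global sizes equal [split_sizes()] exactly.
#'
#' @param items An `image_set`.
#' @param fractions Named fractions (`train`, `test`, `validation`) summing
#'   to 1.
#' @param seed Integer seed.
#' @param stratify Stratify by class (default `TRUE`).
#' @return Named list of three `image_set`s: `train`, `test`, `validation`.
#' @export
split_dataset <- function(items, fractions = c(train = 0.75, test = 0.15,
                                               validation = 0.10),
                          seed = 1L, stratify = TRUE) {
  stopifnot(inherits(items, "image_set"), length(items) >= 3)
  splits <- names(fractions)
  local_seed(seed)
  assign_split <- function(idx) {
    sz <- split_sizes(length(idx), fractions)
    lab <- rep(splits, sz)
    idx_perm <- idx[sample.int(length(idx))]
    stats::setNames(lab, idx_perm)
  }
  if (stratify) {
    pieces <- lapply(split(seq_along(items$labels), items$labels), assign_split)
    assignment <- unlist(unname(pieces))
  } else {
    assignment <- assign_split(seq_along(items$labels))
  }
  idx <- as.integer(names(assignment))
  out <- lapply(stats::setNames(splits, splits), function(s) {
    items[sort(idx[assignment == s])]
  })
  out
}

#' Downsample every class to the least-populated class size
#'
#' Each class is sampled without replacement down to the minimum class
#' size, so the result is balanced and a strict subset of the input.
#'
#' @param items An `image_set`.
#' @param seed Integer seed.
#' @return A balanced `image_set`.
#' @export
balance_classes <- function(items, seed = 1L) {
  stopifnot(inherits(items, "image_set"), length(items) >= 1)
  local_seed(seed)
  sizes <- table(items$labels)
  m <- min(sizes)
  keep <- unlist(lapply(split(seq_along(items$labels), items$labels),
                        function(idx) idx[sample.int(length(idx), m)]))
  items[sort(keep)]
}

#' Normalize an image to 128x128 grayscale in the unit interval
#'
#' Color inputs (H x W x 3 arrays) are converted to luminance
#' (0.2126 R + 0.7152 G + 0.0722 B); any size is rescaled to the target
#' side with bilinear interpolation; intensities are clipped to `[0,1]`.
#' An image already at the target shape passes through unchanged.
#'
#' @param image Numeric matrix or H x W x C array.
#' @param size Target side (default 128).
#' @return `size` x `size` numeric matrix in `[0,1]`.
#' @export
normalize_image <- function(image, size = 128L) {
  if (is.null(dim(image)) || length(image) == 0) {
    stop("empty or corrupt image", call. = FALSE)
  }
  if (length(dim(image)) == 3L) {
    ch <- dim(image)[3]
    image <- if (ch >= 3) {
      0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
    } else {
      image[, , 1]
    }
  }
  if (max(image) > 1.5) image <- image / 255   # 8-bit input
  if (!all(dim(image) == c(size, size))) {
    image <- EBImage::imageData(EBImage::resize(EBImage::Image(image),
                                                w = size, h = size))
  }
  clamp01(image)
}

#' Train-time augmentation configuration
#'
#' Ranges of the three augmentations applied to training images: rotation
#' (degrees), shear (fraction) and luminosity lowering (fraction). The
#' defaults are rotation up to 45 degrees, shear up to 15% and brightness
#' lowering up to 20%.
#'
#' @param rotation Max rotation in degrees, in `[0, 360]`.
#' @param shear Max shear fraction, `>= 0`.
#' @param brightness_lowering Max luminosity drop fraction, in `[0, 1)`.
#' @return An `augmentation_config` object.
#' @export
augmentation_config <- function(rotation = 45, shear = 0.15,
                                brightness_lowering = 0.20) {
  stopifnot(rotation >= 0, rotation <= 360, shear >= 0,
            brightness_lowering >= 0, brightness_lowering < 1)
  structure(list(rotation = rotation, shear = shear,
                 brightness_lowering = brightness_lowering),
            class = "augmentation_config")
}

#' Randomly augment a batch of training images
#'
#' Each image independently receives a rotation drawn uniformly from
#' `[0, rotation]` degrees, a shear from `[0, shear]` and a brightness
#' scale from `[1 - brightness_lowering, 1]`. Rotation and shear are
#' composed into one affine warp about the image centre with bilinear
#' interpolation and dark background fill; output is clipped to `[0,1]`.
#' A config with all ranges at zero is the identity.
#'
#' @param images List of numeric matrices in `[0,1]` (or an `image_set`,
#'   in which case an `image_set` with the same labels is returned).
#' @param config An [augmentation_config()].
#' @param seed Integer seed.
#' @return Augmented images, same container type as the input.
#' @export
augment_batch <- function(images, config = augmentation_config(), seed = 1L) {
  stopifnot(inherits(config, "augmentation_config"))
  is_set <- inherits(images, "image_set")
  imgs <- if (is_set) images$images else images
  if (config$rotation == 0 && config$shear == 0 &&
      config$brightness_lowering == 0) {
    return(images)
  }
  local_seed(seed)
  out <- lapply(imgs, function(img) {
    ang <- stats::runif(1, 0, config$rotation) * pi / 180
    sh <- stats::runif(1, 0, config$shear)
    bright <- 1 - stats::runif(1, 0, config$brightness_lowering)
    if (ang != 0 || sh != 0) {
      h <- nrow(img); w <- ncol(img)
      cxy <- c(w, h) / 2 + 0.5
      ## rotation followed by shear, both about the image centre
      rot <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2)
      shm <- matrix(c(1, 0, sh, 1), 2, 2)
      A <- rot %*% shm
      offset <- cxy - as.vector(A %*% cxy)
      m <- rbind(t(A), offset)
      img <- EBImage::imageData(EBImage::affine(EBImage::Image(img), m,
                                                filter = "bilinear",
                                                bg.col = 0))
    }
    clamp01(img * bright)
  })
  if (is_set) {
    image_set(out, images$labels, classes = images$classes,
              provenance = images$provenance)
  } else {
    out
  }
}
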