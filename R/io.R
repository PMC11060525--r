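# Disk formats: class-per-folder PNG trees with a manifest CSV, counts
# tables and dated control points as CSV, run metadata as JSON.

#' Read a grain image file
#'
#' Reads PNG or TIFF, converts to normalized 128x128 grayscale via
#' [normalize_image()].
#'
#' @param path Image file path.
#' @param size Target side.
#' @return Numeric matrix in `[0,1]`.
#' @export
read_grain_image <- function(path, size = 128L) {
  if (!file.exists(path)) stop("no such image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = as.array(EBImage::readImage(path)),
    stop("unsupported image format: .", ext, call. = FALSE))
  ## PNG arrays arrive row-major (y, x); transpose to the package's (row =
  ## image row) matrix convention consistently
  if (length(dim(img)) == 2) img <- t(img) else img <- aperm(img, c(2, 1, 3))
  normalize_image(img, size = size)
}

#' Write an image set as a class-per-folder PNG tree
#'
#' Writes `<dir>/<split>/<class>/<index>.png` plus `<dir>/manifest.csv`
#' with columns `path,label,split`.
#'
#' @param items An `image_set`.
#' @param dir Output directory.
#' @param split Split name recorded in the manifest (default "all").
#' @return The manifest data frame, invisibly.
#' @export
write_image_set <- function(items, dir, split = "all") {
  stopifnot(inherits(items, "image_set"))
  rows <- vector("list", length(items))
  for (i in seq_along(items$images)) {
    cls <- gsub("[^A-Za-z0-9_.-]+", "_", items$labels[i])
    sub <- file.path(dir, split, cls)
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(sub, sprintf("%06d.png", i))
    png::writePNG(t(items$images[[i]]), path)
    rows[[i]] <- data.frame(path = path, label = items$labels[i],
                            split = split)
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  exists_prior <- file.exists(mpath)
  utils::write.table(manifest, mpath, sep = ",", row.names = FALSE,
                     col.names = !exists_prior, append = exists_prior)
  invisible(manifest)
}

#' Read an image set from a manifest CSV
#'
#' @param manifest Path to a `manifest.csv` (columns `path,label,split`)
#'   or a data frame of the same shape.
#' @param split Optional split filter.
#' @param size Target image side.
#' @return An `image_set`. Unreadable files are skipped with a warning and
#'   reported in the `unreadable` attribute.
#' @export
read_image_set <- function(manifest, split = NULL, size = 128L) {
  m <- if (is.data.frame(manifest)) manifest else {
    utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (!is.null(split)) m <- m[m$split %in% split, ]
  images <- list()
  labels <- character(0)
  unreadable <- character(0)
  for (i in seq_len(nrow(m))) {
    img <- tryCatch(read_grain_image(m$path[i], size = size),
                    error = function(e) NULL)
    if (is.null(img)) {
      unreadable <- c(unreadable, m$path[i])
    } else {
      images <- c(images, list(img))
      labels <- c(labels, m$label[i])
    }
  }
  if (length(unreadable)) {
    warning(length(unreadable), " unreadable image file(s) skipped")
  }
  out <- image_set(images, labels)
  attr(out, "unreadable") <- unreadable
  out
}

#' Write / read a counts table CSV
#'
#' Plain CSV with `sample_id`, `depth_cm`, one column per class,
#' `marker_count`, `volume_cm3`.
#'
#' @param counts Counts data frame.
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_counts <- function(counts, path) {
  utils::write.csv(counts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  counts <- utils::read.csv(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  need <- c("sample_id", "depth_cm")
  if (!all(need %in% names(counts))) {
    stop("counts CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.unsorted(counts$depth_cm, strictly = TRUE) &&
      is.unsorted(rev(counts$depth_cm), strictly = TRUE)) {
    stop("depths must be strictly monotone along the sequence", call. = FALSE)
  }
  cls <- setdiff(names(counts), c("sample_id", "depth_cm", "age_calBP",
                                  "marker_count", "volume_cm3"))
  bad <- cls[vapply(cls, function(cl) any(counts[[cl]] < 0), logical(1))]
  if (length(bad)) stop("negative counts in: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  counts
}

#' Read age-depth control points from CSV
#' @param path CSV with columns `depth_cm`, `age_calBP`.
#' @param kind Interpolation kind for [age_depth_model()].
#' @return An `age_depth_model`.
#' @export
read_age_depth <- function(path, kind = "linear") {
  age_depth_model(utils::read.csv(path), kind = kind)
}

#' Serialize node models to a directory
#'
#' One `.rds`-free plain representation per node is deliberately not
#' attempted; models are R lists of numeric arrays and are written with
#' [saveRDS()] under `<dir>/<node>.model`.
#'
#' @param models Named list of `node_model`s.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_models <- function(models, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(models)) {
    saveRDS(models[[id]], file.path(dir, paste0(gsub("[^A-Za-z0-9_-]+", "_",
                                                     id), ".model")))
  }
  invisible(dir)
}

#' @rdname write_models
#' @export
read_models <- function(dir) {
  files <- list.files(dir, pattern = "\\.model$", full.names = TRUE)
  models <- lapply(files, readRDS)
  names(models) <- vapply(models, function(m) m$node_id, character(1))
  models
}
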