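#' Grayscale image container
#'
#' A `gray_image` is an integer matrix of 8-bit intensities in `[0, 255]`,
#' indexed `(row, col)` with 0-based coordinates in all geometric operations
#' (row 0 is the top row and rows increase downward). Intensities are kept on
#' the native 0-255 scale: the gray-similarity threshold `th_f` of
#' [cluster_params()] is naturally an 8-bit gray difference.
#'
#' @param values numeric or integer matrix; values must be whole numbers in
#'   `[0, 255]`.
#' @return An integer matrix of class `"gray_image"`.
#' @examples
#' img <- gray_image(matrix(c(0, 255, 128, 64), 2, 2))
#' dim(img)
#' @export
gray_image <- function(values) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("image must have height >= 1 and width >= 1", call. = FALSE)
  v <- as.numeric(values)
  if (anyNA(v) || any(v < 0) || any(v > 255) || any(v != round(v)))
    stop("intensities must be integers in [0, 255]", call. = FALSE)
  out <- matrix(as.integer(values), nrow(values), ncol(values))
  class(out) <- c("gray_image", class(out))
  out
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, gray range [%d, %d]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Read an 8-bit grayscale image
#'
#' Reads a PNG or TIFF image. RGB input is converted to luminance
#' (`0.299 R + 0.587 G + 0.114 B`, so equal channels map to the channel
#' value) and rounded to integers in `[0, 255]`.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return A [gray_image()].
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format (need png/tif/tiff): ", path, call. = FALSE)
  )
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] >= 3L) {
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  if (!is.matrix(arr) || length(arr) == 0L)
    stop("zero-sized or undecodable image: ", path, call. = FALSE)
  gray_image(matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr)))
}

#' Write an 8-bit grayscale image as PNG or TIFF
#'
#' @param path output path (`.png`, `.tif` or `.tiff`).
#' @param image a [gray_image()] or integer matrix in `[0, 255]`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(path, image) {
  image <- gray_image(unclass(image))
  m <- matrix(as.numeric(image) / 255, nrow(image), ncol(image))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(m, path),
    tif  = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L),
    stop("unsupported image format (need png/tif/tiff): ", path, call. = FALSE)
  )
  invisible(path)
}

#' Write and read binary masks
#'
#' Masks are stored as 8-bit PNGs with 0 for `FALSE` and 255 for `TRUE`;
#' `read_mask()` recovers the mask as `value > 127`, so round-trips are exact.
#'
#' @param path output PNG path.
#' @param mask a logical matrix.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` returns a
#'   logical matrix.
#' @export
write_mask <- function(path, mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix", call. = FALSE)
  write_gray_image(path, matrix(ifelse(mask, 255L, 0L), nrow(mask), ncol(mask)))
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- read_gray_image(path)
  matrix(unclass(img) > 127L, nrow(img), ncol(img))
}

#' Write and read integer label maps
#'
#' Label ids are packed losslessly into the R and G channels of an RGB PNG
#' (`id = 256 * R + G`), supporting up to 65535 clusters.
#'
#' @param path output PNG path.
#' @param labels an integer matrix of labels in `[0, 65535]`.
#' @return `write_label_map()` returns `path` invisibly; `read_label_map()`
#'   returns an integer matrix.
#' @export
write_label_map <- function(path, labels) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  k <- as.integer(labels)
  if (any(k < 0L) || any(k > 65535L))
    stop("labels must be integers in [0, 65535]", call. = FALSE)
  arr <- array(0, c(nrow(labels), ncol(labels), 3L))
  arr[, , 1] <- (k %/% 256L) / 255
  arr[, , 2] <- (k %% 256L) / 255
  png::writePNG(arr, path)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) != 3L || dim(arr)[3] < 2L)
    stop("not a label-map PNG: ", path, call. = FALSE)
  hi <- round(arr[, , 1] * 255)
  lo <- round(arr[, , 2] * 255)
  matrix(as.integer(hi * 256 + lo), dim(arr)[1], dim(arr)[2])
}

#' Clustering thresholds
#'
#' `th_f` is the gray-value similarity threshold (8-bit intensity units) and
#' `th_o` the spatial proximity threshold (Euclidean pixel distance) of the
#' entanglement criteria: two pixels join one cluster only when both
#' `|f_ij - f_kl| <= th_f` and `sqrt((i-k)^2 + (j-l)^2) <= th_o` hold.
#'
#' @param th_f non-negative gray-difference threshold.
#' @param th_o non-negative pixel-distance threshold.
#' @return A list of class `"cluster_params"`.
#' @export
cluster_params <- function(th_f = 10, th_o = 3) {
  if (!is.numeric(th_f) || length(th_f) != 1L || is.na(th_f) || th_f < 0)
    stop("`th_f` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(th_o) || length(th_o) != 1L || is.na(th_o) || th_o < 0)
    stop("`th_o` must be a single non-negative number", call. = FALSE)
  structure(list(th_f = as.numeric(th_f), th_o = as.numeric(th_o)),
            class = "cluster_params")
}

#' Pixel cluster
#'
#' A labeled set of pixels with its running mean gray value and centroid.
#' Member coordinates are 0-based `(row, col)` pairs.
#'
#' @param id integer cluster id (>= 1).
#' @param members two-column matrix of 0-based `(row, col)` pixel coordinates.
#' @param image the [gray_image()] the pixels belong to.
#' @param kind `"seed"` for clusters formed by the entanglement criteria,
#'   `"pixel-group"` otherwise.
#' @return A list of class `"pixel_cluster"` with fields `id`, `members`,
#'   `mean_gray`, `centroid` (`c(row, col)`), and `kind`.
#' @export
pixel_cluster <- function(id, members, image, kind = "seed") {
  members <- matrix(as.integer(members), ncol = 2L,
                    dimnames = list(NULL, c("row", "col")))
  if (nrow(members) == 0L) stop("cluster members must be non-empty", call. = FALSE)
  kind <- match.arg(kind, c("seed", "pixel-group"))
  h <- nrow(image); w <- ncol(image)
  if (any(members[, 1] < 0L) || any(members[, 1] >= h) ||
      any(members[, 2] < 0L) || any(members[, 2] >= w))
    stop("cluster member outside image bounds", call. = FALSE)
  grays <- unclass(image)[cbind(members[, 1] + 1L, members[, 2] + 1L)]
  structure(list(
    id        = as.integer(id),
    members   = members,
    mean_gray = mean(as.numeric(grays)),
    centroid  = c(mean(members[, 1]), mean(members[, 2])),
    kind      = kind
  ), class = "pixel_cluster")
}

#' @export
print.pixel_cluster <- function(x, ...) {
  cat(sprintf("<pixel_cluster #%d> %d px, mean gray %.2f, centroid (%.2f, %.2f), kind %s\n",
              x$id, nrow(x$members), x$mean_gray, x$centroid[1], x$centroid[2], x$kind))
  invisible(x)
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %s: %d x %d image, %d clusters, %d foreground px, %d sweeps, seed %d\n",
              x$method, nrow(x$labels), ncol(x$labels), length(x$clusters),
              sum(x$foreground), x$iterations_used, x$rng_seed))
  invisible(x)
}

# round-half-up to pixel grid, then clip to image bounds (0-based)
clip_round_pos <- function(pos, h, w) {
  r <- min(max(floor(pos[1] + 0.5), 0), h - 1L)
  c <- min(max(floor(pos[2] + 0.5), 0), w - 1L)
  c(as.integer(r), as.integer(c))
}

clip_pos <- function(pos, h, w) {
  c(min(max(pos[1], 0), h - 1), min(max(pos[2], 0), w - 1))
}
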