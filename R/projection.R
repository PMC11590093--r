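## Biosensor <-> microscope registration.
##
## The two planes are related by a similarity transform without rotation or
## shear: a microscope point m and biosensor point b of the same physical
## location satisfy m = scale * b + translation (both in (row, col) pixel
## coordinates, pixel centers at integers). The scale is nominally the ratio
## of the device resolutions (25 um biosensor pitch over the microscope
## micrometer-per-pixel) and is corrected from user-picked point pairs.

#' Scale-plus-translation transform between the two imaging planes
#'
#' @param scale microscope pixels per biosensor pixel (> 0).
#' @param translation length-2 `(row, col)` offset in microscope pixels.
#' @return an object of class `projection_transform`.
#' @export
projection_transform <- function(scale, translation = c(0, 0)) {
  stopifnot_scalar_number(scale, "scale", positive = TRUE)
  translation <- as.numeric(translation)
  if (length(translation) != 2L || any(!is.finite(translation))) {
    abort("`translation` must be two finite numbers (row, col)")
  }
  structure(list(scale = scale, translation = translation),
            class = "projection_transform")
}

#' @export
print.projection_transform <- function(x, ...) {
  cat(sprintf("<projection_transform> scale %.6g, translation (%.6g, %.6g)\n",
              x$scale, x$translation[1], x$translation[2]))
  invisible(x)
}

#' Estimate the transform from matched coordinate pairs
#'
#' The scale is the mean, over all unordered point pairs, of the ratio of
#' microscope to biosensor inter-point Euclidean distances; the translation
#' is the mean of `m_i - scale * b_i`. With a single pair only the
#' translation can be estimated and `nominal_scale` (from device metadata)
#' is kept.
#'
#' @param pairs data frame with columns `m_row`, `m_col`, `b_row`, `b_col`;
#'   rows are corresponding points on the two planes.
#' @param nominal_scale scale used when fewer than two usable pairs exist.
#' @return a [projection_transform()].
#' @export
estimate_transform <- function(pairs, nominal_scale = NULL) {
  pairs <- as.data.frame(pairs)
  need <- c("m_row", "m_col", "b_row", "b_col")
  if (!all(need %in% names(pairs))) {
    abort("`pairs` needs columns m_row, m_col, b_row, b_col")
  }
  n <- nrow(pairs)
  if (n < 1) abort("at least one coordinate pair is required")
  m <- as.matrix(pairs[, c("m_row", "m_col")])
  b <- as.matrix(pairs[, c("b_row", "b_col")])
  if (anyDuplicated(b) && n > 1) abort("duplicate biosensor points in `pairs`")

  if (n >= 2) {
    ratios <- c()
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        db <- sqrt(sum((b[i, ] - b[j, ])^2))
        dm <- sqrt(sum((m[i, ] - m[j, ])^2))
        if (db > 0) ratios <- c(ratios, dm / db)
      }
    }
    if (length(ratios) == 0) {
      abort("all point pairs have coincident biosensor coordinates")
    }
    scale <- mean(ratios)
  } else {
    if (is.null(nominal_scale)) {
      abort("one pair estimates translation only; supply `nominal_scale`")
    }
    scale <- nominal_scale
  }
  translation <- colMeans(m - scale * b)
  projection_transform(scale, translation)
}

#' Project points between the two planes
#'
#' @param points 2-column `(row, col)` matrix or data frame.
#' @param transform a [projection_transform()].
#' @param direction `"b2m"` (biosensor to microscope, the forward map) or
#'   `"m2b"` (its inverse).
#' @return matrix of projected points.
#' @export
project_points <- function(points, transform, direction = c("b2m", "m2b")) {
  direction <- match.arg(direction)
  stopifnot(inherits(transform, "projection_transform"))
  p <- as.matrix(as.data.frame(points))[, 1:2, drop = FALSE]
  tr <- matrix(transform$translation, nrow(p), 2, byrow = TRUE)
  out <- if (direction == "b2m") {
    transform$scale * p + tr
  } else {
    (p - tr) / transform$scale
  }
  colnames(out) <- c("row", "col")
  out
}

#' Project a microscope label mask onto the biosensor grid
#'
#' Each microscope pixel center of cell k is inverse-mapped to the biosensor
#' plane; a biosensor pixel belongs to cell k's cover if at least one mapped
#' center falls inside its unit square. Pixels outside the sensor grid are
#' discarded. Where two cells cover the same biosensor pixel, both keep it in
#' their pixel sets, but the single-valued output mask assigns the pixel to
#' the cell contributing more microscope pixels.
#'
#' @param mask a `label_mask` on the microscope plane.
#' @param transform a [projection_transform()].
#' @param sensor_shape biosensor grid dimensions, default `c(80, 80)`.
#' @return a list: `pixel_sets` (named list of `(row, col)` matrices, one
#'   per cell id) and `mask` (a biosensor-plane `label_mask`).
#' @export
project_mask_to_biosensor <- function(mask, transform, sensor_shape = c(80, 80)) {
  stopifnot(inherits(mask, "label_mask"), inherits(transform, "projection_transform"))
  labs <- sort(setdiff(unique(as.vector(mask$labels)), 0L))
  counts_env <- new.env(parent = emptyenv())
  pixel_sets <- stats::setNames(vector("list", length(labs)), as.character(labs))
  # per-(biosensor pixel, cell) microscope-pixel counts
  votes <- array(0L, c(sensor_shape[1], sensor_shape[2]))
  best <- array(0L, c(sensor_shape[1], sensor_shape[2]))
  for (k in labs) {
    mpx <- which(mask$labels == k, arr.ind = TRUE)
    bpx <- round(project_points(mpx, transform, "m2b"))
    keep <- bpx[, 1] >= 1 & bpx[, 1] <= sensor_shape[1] &
      bpx[, 2] >= 1 & bpx[, 2] <= sensor_shape[2]
    bpx <- bpx[keep, , drop = FALSE]
    if (nrow(bpx) == 0) {
      pixel_sets[[as.character(k)]] <- matrix(integer(0), 0, 2,
                                              dimnames = list(NULL, c("row", "col")))
      next
    }
    key <- paste(bpx[, 1], bpx[, 2])
    cnt <- table(key)
    upx <- unique(bpx)
    pixel_sets[[as.character(k)]] <- upx
    for (r in seq_len(nrow(upx))) {
      i <- upx[r, 1]; j <- upx[r, 2]
      c_kr <- as.integer(cnt[[paste(i, j)]])
      if (c_kr > votes[i, j]) {
        votes[i, j] <- c_kr
        best[i, j] <- k
      }
    }
  }
  list(pixel_sets = pixel_sets,
       mask = label_mask(best, pixel_size = 25))
}

#' Crop a microscope image to the projected sensor area
#'
#' The sensor rectangle (pixel squares `[0.5, n + 0.5]` on the biosensor
#' plane) is forward-projected and clipped to the image; the crop offset is
#' returned so mask/point coordinates can be kept consistent via the adjusted
#' transform.
#'
#' @param image microscope matrix.
#' @param transform a [projection_transform()].
#' @param sensor_shape biosensor grid dimensions.
#' @return a list: `image` (cropped), `offset` (`(row, col)` of the crop's
#'   first pixel minus 1), `transform` (transform valid in cropped
#'   coordinates).
#' @export
crop_to_sensor <- function(image, transform, sensor_shape = c(80, 80)) {
  stopifnot(is.matrix(image), inherits(transform, "projection_transform"))
  # half-open pixel-center convention [lo, hi): an s-scaled n-pixel sensor
  # spans exactly n * s microscope pixels
  lo <- transform$scale * 0.5 + transform$translation
  hi <- transform$scale * (sensor_shape + 0.5) + transform$translation
  r1 <- max(1L, ceiling(lo[1])); r2 <- min(nrow(image), ceiling(hi[1]) - 1)
  c1 <- max(1L, ceiling(lo[2])); c2 <- min(ncol(image), ceiling(hi[2]) - 1)
  if (r1 > r2 || c1 > c2) abort("projected sensor area does not intersect the image")
  offset <- c(r1 - 1L, c1 - 1L)
  list(
    image = image[r1:r2, c1:c2, drop = FALSE],
    offset = offset,
    transform = projection_transform(transform$scale,
                                     transform$translation - offset)
  )
}

#' Write / read a transform as JSON
#'
#' @param transform a [projection_transform()].
#' @param path JSON file path.
#' @param extra optional named list stored alongside the transform.
#' @return the path / a list with `transform` and `extra`.
#' @export
write_transform <- function(transform, path, extra = list()) {
  stopifnot(inherits(transform, "projection_transform"))
  jsonlite::write_json(
    c(list(scale = transform$scale, translation = transform$translation), extra),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tf <- projection_transform(obj$scale, obj$translation)
  obj$scale <- NULL; obj$translation <- NULL
  list(transform = tf, extra = obj)
}
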