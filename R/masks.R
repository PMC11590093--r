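## Label-mask I/O and utilities.
##
## Masks come from an external segmenter (Cellpose-style, or manual
## annotation) as integer-labelled images: 0 = background, k >= 1 = cell k.
## A simple built-in threshold segmenter is provided so the pipeline runs
## end-to-end without external tools.

#' Construct a label mask
#'
#' @param labels integer matrix; 0 is background, each positive value labels
#'   one cell.
#' @param pixel_size physical pixel size in micrometers (25 for the
#'   biosensor plane).
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(labels, pixel_size = NA_real_) {
  if (!is.matrix(labels)) abort("`labels` must be a matrix")
  if (is.double(labels)) {
    if (any(labels != floor(labels))) abort("label values must be integers")
    storage.mode(labels) <- "integer"
  }
  if (any(labels < 0)) abort("label values must be non-negative")
  structure(list(labels = labels, pixel_size = pixel_size), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px, %d cells\n",
              nrow(x$labels), ncol(x$labels), n_cells(x)))
  invisible(x)
}

#' Number of distinct cells in a mask
#' @param mask a `label_mask`.
#' @export
n_cells <- function(mask) length(setdiff(unique(as.vector(mask$labels)), 0L))

#' Read / write label masks
#'
#' Masks are stored as 16-bit integer TIFF (or read from integer PNG);
#' round-trips are bit-exact. Float-valued images are rejected: a mask is a
#' set of identifiers, not a measurement.
#'
#' @param path TIFF or PNG path.
#' @param pixel_size optional micrometer pixel size attached on read.
#' @return `read_mask()` a `label_mask`; `write_mask()` the path, invisibly.
#' @export
read_mask <- function(path, pixel_size = NA_real_) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path) * 65535
  } else {
    info <- tiff::readTIFF(path, payload = FALSE)
    if (info$bits.per.sample > 16) {
      abort(sprintf(
        "'%s' has %d-bit samples (float or wavelength data); not a label mask",
        path, info$bits.per.sample))
    }
    tiff::readTIFF(path, as.is = TRUE)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  if (any(abs(img - round(img)) > 1e-6)) {
    abort(sprintf("'%s' contains non-integer pixels; not a label mask", path))
  }
  label_mask(matrix(as.integer(round(img)), nrow(img), ncol(img)),
             pixel_size = pixel_size)
}

#' @rdname read_mask
#' @param mask a `label_mask` to write.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask$labels) > 65535L) abort("label ids exceed 16-bit storage")
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' Split an image (or mask) into a grid of tiles
#'
#' Microscope frames are tiled (2 x 2 by default) to keep training images
#' small; tiles carry their origin so they reassemble exactly. Dimensions not
#' divisible by the grid are zero-padded and the padding recorded.
#'
#' @param image matrix, or a `label_mask`.
#' @param grid `(rows, cols)` tile layout.
#' @return a list of class `tile_set`: `tiles` (row-major list of matrices),
#'   `grid`, `original_dim`, `padded_dim`.
#' @export
tile_image <- function(image, grid = c(2, 2)) {
  is_mask <- inherits(image, "label_mask")
  mat <- if (is_mask) image$labels else image
  stopifnot(is.matrix(mat))
  od <- dim(mat)
  pd <- as.integer(ceiling(od / grid) * grid)
  if (any(pd != od)) {
    pad <- matrix(0, pd[1], pd[2])
    storage.mode(pad) <- storage.mode(mat)
    pad[seq_len(od[1]), seq_len(od[2])] <- mat
    mat <- pad
  }
  th <- pd[1] / grid[1]; tw <- pd[2] / grid[2]
  tiles <- list()
  for (i in seq_len(grid[1])) {
    for (j in seq_len(grid[2])) {
      tiles[[length(tiles) + 1L]] <-
        mat[(i - 1) * th + seq_len(th), (j - 1) * tw + seq_len(tw)]
    }
  }
  structure(list(tiles = tiles, grid = as.integer(grid), original_dim = od,
                 padded_dim = pd, is_mask = is_mask),
            class = "tile_set")
}

#' Reassemble tiles produced by [tile_image()]
#' @param tile_set a `tile_set`.
#' @return the original matrix (padding removed), or `label_mask` if the
#'   input was one.
#' @export
untile_image <- function(tile_set) {
  stopifnot(inherits(tile_set, "tile_set"))
  g <- tile_set$grid; pd <- tile_set$padded_dim
  th <- pd[1] / g[1]; tw <- pd[2] / g[2]
  out <- matrix(vector(typeof(tile_set$tiles[[1]]), 1), pd[1], pd[2])
  k <- 0L
  for (i in seq_len(g[1])) {
    for (j in seq_len(g[2])) {
      k <- k + 1L
      out[(i - 1) * th + seq_len(th), (j - 1) * tw + seq_len(tw)] <- tile_set$tiles[[k]]
    }
  }
  out <- out[seq_len(tile_set$original_dim[1]), seq_len(tile_set$original_dim[2])]
  if (tile_set$is_mask) label_mask(out) else out
}

#' Threshold-based fallback segmenter
#'
#' A deliberately simple mask provider (Gaussian smooth, global threshold,
#' connected components, small-object removal) so the pipeline has no hard
#' dependency on an external deep-learning segmenter. Adequate for
#' well-separated cells on a clean background; not a replacement for a
#' trained model on crowded phase-contrast images.
#'
#' @param image grayscale matrix.
#' @param smooth_sigma Gaussian blur sigma in px (0 = no smoothing).
#' @param threshold foreground threshold on the smoothed image.
#' @param min_area components smaller than this many pixels are dropped.
#' @return a `label_mask` with sequential labels (possibly empty).
#' @export
fallback_segment <- function(image, smooth_sigma = 2, threshold = 0.5, min_area = 9) {
  stopifnot(is.matrix(image))
  sm <- if (smooth_sigma > 0) EBImage::gblur(image, sigma = smooth_sigma) else image
  fg <- sm > threshold
  lab <- EBImage::bwlabel(fg)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(areas >= min_area)
    relab <- integer(max(lab))
    relab[keep] <- seq_along(keep)
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  label_mask(lab)
}

#' Filter mask cells by area
#'
#' @param mask a `label_mask`.
#' @param min_area,max_area inclusive pixel-area bounds; survivors keep their
#'   original label ids.
#' @return filtered `label_mask`.
#' @export
filter_mask <- function(mask, min_area = 0, max_area = Inf) {
  stopifnot(inherits(mask, "label_mask"))
  if (min_area > max_area) abort("`min_area` must not exceed `max_area`")
  lab <- mask$labels
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(areas > 0 & (areas < min_area | areas > max_area))
    lab[lab %in% drop] <- 0L
  }
  label_mask(lab, pixel_size = mask$pixel_size)
}
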