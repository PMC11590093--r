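## Biosensor preprocessing: mosaic -> per-well, adhesion-aligned, offset-,
## outlier- and background-corrected wavelength-shift videos.

#' Split a (T, 240, 320) mosaic into individual wells
#'
#' The Epic Cardio mosaic tiles 12 wells of 80 x 80 px in a 3 x 4
#' arrangement; well `(i, j)` is the block `[, 80(i-1)+1:80, 80(j-1)+1:80]`.
#'
#' @param video `(T, 240, 320)` pm array (or any `80 * grid` mosaic).
#' @param timeline per-frame timestamps in seconds, same length as frames.
#' @param grid well layout, default `c(3, 4)`.
#' @return a named list of `well_video` objects (`A1`, `A2`, ..., row-major),
#'   each holding `video` `(T, 80, 80)`, `timeline`, `well_id`, and empty
#'   outlier/background annotations.
#' @export
split_wells <- function(video, timeline, grid = c(3, 4)) {
  d <- dim(video)
  if (length(d) != 3L || d[2] != 80 * grid[1] || d[3] != 80 * grid[2]) {
    abort(sprintf("expected a (T, %d, %d) mosaic, got (%s)",
                  80 * grid[1], 80 * grid[2], paste(d, collapse = ", ")))
  }
  if (length(timeline) != d[1]) abort("timeline length must match frame count")
  if (any(diff(timeline) <= 0)) abort("timeline must be strictly increasing")
  wells <- list()
  for (i in seq_len(grid[1])) {
    for (j in seq_len(grid[2])) {
      wid <- sprintf("%s%d", LETTERS[i], j)
      wells[[wid]] <- new_well_video(
        video[, (i - 1) * 80 + seq_len(80), (j - 1) * 80 + seq_len(80), drop = FALSE],
        timeline = timeline, well_id = wid
      )
    }
  }
  wells
}

new_well_video <- function(video, timeline, well_id,
                           outlier_mask = NULL, background_pixels = NULL,
                           start_index = NA_integer_) {
  structure(
    list(video = video, timeline = timeline, well_id = well_id,
         outlier_mask = outlier_mask %||% matrix(FALSE, dim(video)[2], dim(video)[3]),
         background_pixels = background_pixels,
         start_index = start_index),
    class = "well_video"
  )
}

#' @export
print.well_video <- function(x, ...) {
  cat(sprintf("<well_video %s> %d frames, %d x %d px, %d outlier px, %s background px\n",
              x$well_id, dim(x$video)[1], dim(x$video)[2], dim(x$video)[3],
              sum(x$outlier_mask),
              if (is.null(x$background_pixels)) "no" else nrow(x$background_pixels)))
  invisible(x)
}

#' Locate the adhesion start from pipetting gaps in the timeline
#'
#' Cells are pipetted into the wells partway through the recording; the
#' pause shows up as a large inter-frame gap in the exported timeline. The
#' start frame is the first frame after the largest gap exceeding
#' `gap_factor` times the median scan interval.
#'
#' @param timeline timestamps in seconds (>= 3 values).
#' @param gap_factor multiple of the median inter-frame interval a gap must
#'   exceed; pipetting pauses are minutes against ~seconds scans.
#' @return 1-based index of the first adhesion frame.
#' @export
detect_adhesion_start <- function(timeline, gap_factor = 10) {
  if (length(timeline) < 3) abort("need at least 3 timestamps")
  gaps <- diff(timeline)
  thr <- gap_factor * median(gaps)
  big <- which(gaps > thr)
  if (length(big) == 0) {
    abort(paste0("no inter-frame gap exceeds ", gap_factor,
                 "x the median interval; pass the start frame explicitly"))
  }
  best <- big[which.max(gaps[big])]
  best + 1L
}

#' Trim a well (or all wells) to the adhesion phase
#'
#' Frames before `start` are dropped and the timeline re-zeroed at the first
#' retained frame.
#'
#' @param well a `well_video`.
#' @param start first adhesion frame, e.g. from [detect_adhesion_start()].
#' @return trimmed `well_video`.
#' @export
trim_well <- function(well, start) {
  stopifnot(inherits(well, "well_video"))
  T_all <- dim(well$video)[1]
  if (start < 1 || start > T_all) abort("start index outside the recording")
  keep <- start:T_all
  new_well_video(well$video[keep, , , drop = FALSE],
                 timeline = well$timeline[keep] - well$timeline[start],
                 well_id = well$well_id,
                 outlier_mask = well$outlier_mask,
                 background_pixels = well$background_pixels,
                 start_index = as.integer(start))
}

#' Offset correction: subtract the first frame
#'
#' Removes the per-pixel static offset by subtracting the first (trimmed)
#' frame from every frame; frame 1 becomes identically zero. The raw first
#' frame is kept on the object (`raw_first`) because static sensor
#' artifacts — the target of [mask_outliers()] — are only visible before
#' subtraction.
#'
#' @param well a trimmed `well_video`.
#' @return corrected `well_video`.
#' @export
offset_correct <- function(well) {
  stopifnot(inherits(well, "well_video"))
  v <- well$video
  first <- v[1, , ]
  for (t in seq_len(dim(v)[1])) v[t, , ] <- v[t, , ] - first
  well$video <- v
  well$raw_first <- first
  well
}

#' Per-pixel kinetic (reference) image of a well
#'
#' The per-pixel maximum over time of the corrected video. Used as the
#' reference for outlier statistics, the 75 pm foreground threshold and the
#' local-maxima search; the max-projection is robust to late-adhering cells.
#'
#' @param well a `well_video`.
#' @return 80 x 80 matrix in pm.
#' @export
kinetic_image <- function(well) {
  stopifnot(inherits(well, "well_video"))
  apply(well$video, c(2, 3), max)
}

#' Mask spatial outliers
#'
#' Flags pixels whose raw pre-correction value lies outside
#' `mean +/- k * sd` of the unmasked pixels and excludes them from all
#' subsequent statistics. This removes the static resonance artifacts where
#' the sensor intersects the well boundary; those artifacts dwarf any cell
#' signal (tens of thousands vs hundreds of pm) and are present before
#' adhesion, so the statistics are taken on the raw first frame (stored by
#' [offset_correct()]) where adhering cells cannot be mistaken for
#' outliers.
#'
#' @param well an offset-corrected `well_video`.
#' @param k standard-deviation multiple, default 3.
#' @return `well_video` with `outlier_mask` set.
#' @export
mask_outliers <- function(well, k = 3) {
  stopifnot(inherits(well, "well_video"))
  ref <- well$raw_first
  if (is.null(ref)) {
    abort("no raw first frame on this well; run offset_correct() first")
  }
  vals <- ref[!well$outlier_mask]
  mu <- mean(vals); s <- sd(vals)
  if (!is.finite(s) || s == 0) return(well)  # degenerate: nothing to mask
  out <- (ref < mu - k * s) | (ref > mu + k * s)
  well$outlier_mask <- well$outlier_mask | out
  well
}

#' Pseudorandom background pixel selection
#'
#' Picks up to `n` unmasked pixels below the 75 pm foreground threshold that
#' keep a minimum Euclidean distance both from any foreground pixel and from
#' each other. Sampling is weighted toward the well center (Gaussian weight)
#' to avoid edge artifacts, and is deterministic for a fixed seed.
#'
#' @param well an offset-corrected, outlier-masked `well_video`.
#' @param threshold absolute wavelength-shift foreground threshold, pm.
#' @param n number of background pixels requested.
#' @param min_dist_fg minimum distance from any foreground pixel, px.
#' @param min_dist_bg minimum pairwise distance between selected pixels, px.
#' @param center_sigma Gaussian center-weighting width, px.
#' @param min_candidates error if fewer candidates than this survive the
#'   distance and threshold constraints ("well too confluent").
#' @param seed RNG seed.
#' @return `well_video` with `background_pixels` set to a `(row, col)`
#'   matrix of at most `n` pixels.
#' @export
select_background_pixels <- function(well, threshold = 75, n = 100,
                                     min_dist_fg = 2, min_dist_bg = 2,
                                     center_sigma = 20, min_candidates = 10,
                                     seed = 1) {
  stopifnot(inherits(well, "well_video"))
  ref <- kinetic_image(well)
  h <- nrow(ref); w <- ncol(ref)
  fg <- abs(ref) >= threshold & !well$outlier_mask
  candidate <- abs(ref) < threshold & !well$outlier_mask

  if (any(fg)) {
    # distance of every pixel to the nearest foreground pixel
    dist_fg <- EBImage::distmap(matrix(as.numeric(!fg), h, w))
    dist_fg <- matrix(as.numeric(dist_fg), h, w)
    candidate <- candidate & (dist_fg >= min_dist_fg)
  }
  idx <- which(candidate, arr.ind = TRUE)
  if (nrow(idx) < min_candidates) {
    abort(sprintf("only %d background candidates; well too confluent", nrow(idx)))
  }
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  wgt <- exp(-((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2) / (2 * center_sigma^2))

  with_seed(seed, {
    chosen <- matrix(numeric(0), 0, 2)
    avail <- rep(TRUE, nrow(idx))
    while (nrow(chosen) < n && any(avail)) {
      pool <- which(avail)
      pick <- if (length(pool) == 1) pool else sample(pool, 1, prob = wgt[pool])
      p <- idx[pick, ]
      chosen <- rbind(chosen, p)
      d <- sqrt((idx[, 1] - p[1])^2 + (idx[, 2] - p[2])^2)
      avail <- avail & (d >= min_dist_bg)
    }
    colnames(chosen) <- c("row", "col")
    rownames(chosen) <- NULL
    well$background_pixels <- chosen
    well
  })
}

#' Background correction
#'
#' Subtracts, frame by frame, the mean wavelength shift over the selected
#' background pixels from every pixel of that frame, removing global drift.
#' After correction the per-frame mean over the background pixels is zero to
#' numerical precision.
#'
#' @param well a `well_video` with `background_pixels` set (or pass `pixels`).
#' @param pixels optional `(row, col)` matrix overriding the stored set.
#' @return corrected `well_video`.
#' @export
correct_background <- function(well, pixels = NULL) {
  stopifnot(inherits(well, "well_video"))
  pixels <- pixels %||% well$background_pixels
  if (is.null(pixels) || nrow(pixels) == 0) {
    abort("no background pixels; run select_background_pixels() first")
  }
  v <- well$video
  flat_idx <- (pixels[, 2] - 1) * dim(v)[2] + pixels[, 1]
  for (t in seq_len(dim(v)[1])) {
    fr <- v[t, , ]
    v[t, , ] <- fr - mean(fr[flat_idx])
  }
  well$video <- v
  well$background_pixels <- pixels
  well
}

#' Full preprocessing pipeline for one recording
#'
#' split -> trim (timeline gap detection) -> offset correction -> outlier
#' masking -> background selection and subtraction, per well. Deterministic
#' given `seed`.
#'
#' @param video `(T, 240, 320)` mosaic in pm.
#' @param timeline timestamps in seconds.
#' @param start optional explicit adhesion start frame (skips detection).
#' @param grid well layout.
#' @param threshold foreground threshold in pm.
#' @param k outlier sd multiple.
#' @param n_background background pixels per well.
#' @param seed RNG seed for background selection.
#' @param wells optional character vector restricting which wells to process.
#' @return named list of corrected `well_video` objects.
#' @export
preprocess_recording <- function(video, timeline, start = NULL, grid = c(3, 4),
                                 threshold = 75, k = 3, n_background = 100,
                                 seed = 1, wells = NULL) {
  ws <- split_wells(video, timeline, grid = grid)
  if (!is.null(wells)) ws <- ws[intersect(names(ws), wells)]
  start <- start %||% detect_adhesion_start(timeline)
  out <- list()
  for (wid in names(ws)) {
    w <- trim_well(ws[[wid]], start)
    w <- offset_correct(w)
    w <- mask_outliers(w, k = k)
    w <- select_background_pixels(w, threshold = threshold, n = n_background,
                                  seed = seed)
    out[[wid]] <- correct_background(w)
  }
  out
}
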