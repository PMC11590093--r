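## Wavelength-shift TIFF I/O.
##
## The Epic Cardio exports wavelength shifts in picometers with a 0.25 pm scan
## step; R's `tiff` package stores samples scaled to [0, 1]. Videos are
## therefore encoded with a fixed-quantum integer codec: each pm value is
## mapped to k = round(pm / 2^-12) + 2^30 and written as a 32-bit sample.
## The representable range is +/- 2^18 pm with a 2^-12 pm (~0.00024 pm) step,
## orders of magnitude below sensor noise. Any value on the codec grid (which
## includes the instrument's 0.25 pm grid) round-trips bit-exactly.

PM_QUANTUM <- 2^-12
PM_OFFSET <- 2^30
PM_SCALE <- 2^32 - 1

pm_encode <- function(x) {
  k <- round(x / PM_QUANTUM) + PM_OFFSET
  if (any(k < 0 | k >= 2^31, na.rm = TRUE)) {
    abort("wavelength-shift values outside the representable +/-262144 pm range")
  }
  k / PM_SCALE
}

pm_decode <- function(k) {
  (as.numeric(k) - PM_OFFSET) * PM_QUANTUM
}

#' Write a wavelength-shift video as a multi-frame TIFF
#'
#' Frames are stored as 32-bit samples through a fixed-quantum picometer
#' codec with a 2^-12 pm step, so instrument-grid values (0.25 pm step)
#' round-trip bit-exactly and arbitrary values are preserved to within half a
#' quantum on first write (and exactly thereafter).
#'
#' @param video numeric array `(T, H, W)` of wavelength shifts in picometers.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_ws_tiff()]
#' @export
write_ws_tiff <- function(video, path) {
  stopifnot(is.array(video), length(dim(video)) == 3L)
  frames <- lapply(seq_len(dim(video)[1]), function(t) pm_encode(video[t, , ]))
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' Read a wavelength-shift video written by [write_ws_tiff()]
#'
#' @param path multi-frame TIFF path.
#' @return numeric array `(T, H, W)` in picometers.
#' @export
read_ws_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  out <- array(NA_real_, c(length(frames), h, w))
  for (t in seq_along(frames)) out[t, , ] <- pm_decode(frames[[t]])
  out
}

#' Write / read an instrument timeline
#'
#' The timeline is the per-frame acquisition timestamp in seconds exported by
#' the instrument; pipetting pauses appear as large gaps and are used to
#' locate the start of the adhesion phase.
#'
#' @param timeline numeric vector of timestamps in seconds.
#' @param path CSV path with columns `frame_index` (1-based) and `t_seconds`.
#' @return `path` invisibly for the writer; a numeric vector for the reader.
#' @export
write_timeline_csv <- function(timeline, path) {
  readr::write_csv(
    tibble(frame_index = seq_along(timeline), t_seconds = timeline),
    path
  )
  invisible(path)
}

#' @rdname write_timeline_csv
#' @export
read_timeline_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  df$t_seconds[order(df$frame_index)]
}
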