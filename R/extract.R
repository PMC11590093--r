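## Single-cell selection on the aligned biosensor plane and (t, 8, 8)
## sample extraction.
##
## Three strategies: M (cover pixels of manually annotated microscope
## masks), P (same, with predicted masks), W (watershed on the biosensor
## kinetic image seeded by local maxima).

#' Local maxima of a kinetic image
#'
#' Returns pixels that are neighborhood maxima within a `min_distance`
#' Chebyshev radius and whose value lies in
#' `[lower_threshold, upper_threshold]`. A completely flat neighborhood is
#' not a peak; plateau ties are otherwise broken in (row, col)
#' lexicographic order, keeping the first pixel.
#'
#' @param image matrix, typically [kinetic_image()] of a corrected well.
#' @param lower_threshold,upper_threshold inclusive value bounds; the lower
#'   default reuses the 75 pm foreground threshold.
#' @param min_distance neighborhood radius in px.
#' @return `(row, col)` integer matrix of maxima (possibly 0 rows).
#' @export
find_local_maxima <- function(image, lower_threshold = 75,
                              upper_threshold = Inf, min_distance = 2) {
  stopifnot(is.matrix(image))
  h <- nrow(image); w <- ncol(image)
  cand <- which(image >= lower_threshold & image <= upper_threshold, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  }
  # lexicographic (row, col) order so plateau ties keep the first pixel
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    rs <- max(1, r - min_distance):min(h, r + min_distance)
    cs <- max(1, c - min_distance):min(w, c + min_distance)
    nb <- image[rs, cs]
    v <- image[r, c]
    if (v < max(nb)) next
    if (!any(nb < v)) next  # entirely flat neighborhood: not a peak
    # plateau handling: reject if an equal-valued pixel earlier in
    # lexicographic order lies in the neighborhood
    eq <- which(nb == v, arr.ind = TRUE)
    eq_r <- rs[eq[, 1]]; eq_c <- cs[eq[, 2]]
    first <- order(eq_r, eq_c)[1]
    keep[i] <- (eq_r[first] == r && eq_c[first] == c)
  }
  out <- cand[keep, , drop = FALSE]
  colnames(out) <- c("row", "col")
  out
}

#' Marker-controlled watershed on the biosensor kinetic image
#'
#' Foreground is the superlevel set at `lower_threshold`; its Euclidean
#' distance transform is negated and flooded from the seed pixels
#' (priority-flood). Each output region is connected (8-neighborhood),
#' contains exactly one seed, and the regions partition the foreground.
#'
#' @param image kinetic image matrix, pm.
#' @param seeds `(row, col)` matrix from [find_local_maxima()].
#' @param lower_threshold foreground threshold, pm.
#' @return a biosensor-plane `label_mask`; label i corresponds to seed row i.
#' @export
watershed_segment <- function(image, seeds, lower_threshold = 75) {
  stopifnot(is.matrix(image))
  h <- nrow(image); w <- ncol(image)
  lab <- matrix(0L, h, w)
  if (NROW(seeds) == 0) return(label_mask(lab, pixel_size = 25))
  fg <- image >= lower_threshold
  dm <- EBImage::distmap(matrix(as.numeric(fg), h, w))
  dm <- matrix(as.numeric(dm), h, w)

  prio <- -dm  # flood from high distance (cell cores) outward
  n_px <- h * w
  heap_idx <- integer(0); heap_key <- numeric(0)  # simple binary heap
  push <- function(i, key) {
    heap_idx[length(heap_idx) + 1L] <<- i
    heap_key[length(heap_key) + 1L] <<- key
    k <- length(heap_idx)
    while (k > 1) {
      p <- k %/% 2L
      if (heap_key[p] <= heap_key[k]) break
      tmp <- heap_idx[p]; heap_idx[p] <<- heap_idx[k]; heap_idx[k] <<- tmp
      tmpk <- heap_key[p]; heap_key[p] <<- heap_key[k]; heap_key[k] <<- tmpk
      k <- p
    }
  }
  pop <- function() {
    top <- heap_idx[1]
    n <- length(heap_idx)
    heap_idx[1] <<- heap_idx[n]; heap_key[1] <<- heap_key[n]
    heap_idx <<- heap_idx[-n]; heap_key <<- heap_key[-n]
    k <- 1L; n <- n - 1L
    repeat {
      l <- 2L * k; r <- l + 1L
      s <- k
      if (l <= n && heap_key[l] < heap_key[s]) s <- l
      if (r <= n && heap_key[r] < heap_key[s]) s <- r
      if (s == k) break
      tmp <- heap_idx[s]; heap_idx[s] <<- heap_idx[k]; heap_idx[k] <<- tmp
      tmpk <- heap_key[s]; heap_key[s] <<- heap_key[k]; heap_key[k] <<- tmpk
      k <- s
    }
    top
  }

  in_queue <- logical(n_px)
  for (i in seq_len(nrow(seeds))) {
    r <- seeds[i, 1]; c <- seeds[i, 2]
    if (!fg[r, c]) next  # seed below threshold: no region
    p <- (c - 1L) * h + r
    lab[p] <- i
    push(p, prio[p])
    in_queue[p] <- TRUE
  }
  off_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  while (length(heap_idx) > 0) {
    p <- pop()
    r <- ((p - 1L) %% h) + 1L
    c <- ((p - 1L) %/% h) + 1L
    lp <- lab[p]
    for (k in 1:8) {
      rr <- r + off_r[k]; cc <- c + off_c[k]
      if (rr < 1 || rr > h || cc < 1 || cc > w) next
      q <- (cc - 1L) * h + rr
      if (!fg[q] || lab[q] != 0L || in_queue[q]) next
      lab[q] <- lp
      push(q, prio[q])
      in_queue[q] <- TRUE
    }
  }
  label_mask(lab, pixel_size = 25)
}

#' Build single-cell candidates from a segmentation source
#'
#' One candidate per labelled region: centroid (pixel-set centroid rounded
#' to the nearest grid pixel), area, maximum adhesion (max over time and
#' pixel set of the well video) and distance of the centroid to the nearest
#' well border.
#'
#' @param well a corrected `well_video`.
#' @param source either the result of [project_mask_to_biosensor()] (list
#'   with `pixel_sets`), a biosensor-plane `label_mask`, or a named list of
#'   `(row, col)` pixel matrices.
#' @param strategy provenance tag `"M"`, `"P"` or `"W"`.
#' @return a candidates tibble: `well_id`, `cell_id`, `strategy`,
#'   `centroid_row`, `centroid_col`, `area`, `max_adhesion`,
#'   `edge_distance`, and a `pixel_set` list-column.
#' @export
build_candidates <- function(well, source, strategy = c("M", "P", "W")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(well, "well_video"))
  sets <- if (inherits(source, "label_mask")) {
    labs <- sort(setdiff(unique(as.vector(source$labels)), 0L))
    stats::setNames(
      lapply(labs, function(k) {
        px <- which(source$labels == k, arr.ind = TRUE)
        colnames(px) <- c("row", "col")
        px
      }),
      as.character(labs))
  } else if (is.list(source) && !is.null(source$pixel_sets)) {
    source$pixel_sets
  } else {
    source
  }
  h <- dim(well$video)[2]; w <- dim(well$video)[3]
  vmat <- matrix(well$video, dim(well$video)[1], h * w)
  rows <- list()
  for (nm in names(sets)) {
    px <- sets[[nm]]
    if (NROW(px) == 0) next
    ctr <- unname(round(colMeans(px[, 1:2, drop = FALSE])))
    flat <- (px[, 2] - 1) * h + px[, 1]
    vmax <- max(vmat[, flat])
    rows[[length(rows) + 1L]] <- tibble(
      well_id = well$well_id, cell_id = as.integer(nm), strategy = strategy,
      centroid_row = ctr[1], centroid_col = ctr[2],
      area = nrow(px), max_adhesion = vmax,
      edge_distance = min(ctr[1] - 1, ctr[2] - 1, h - ctr[1], w - ctr[2]),
      pixel_set = list(px)
    )
  }
  if (length(rows)) dplyr::bind_rows(rows) else empty_candidates()
}

empty_candidates <- function() {
  tibble(well_id = character(), cell_id = integer(), strategy = character(),
         centroid_row = double(), centroid_col = double(),
         area = integer(), max_adhesion = double(), edge_distance = double(),
         pixel_set = list())
}

#' Filter candidates by per-cell properties
#'
#' @param candidates a candidates tibble from [build_candidates()].
#' @param min_area,max_area inclusive area bounds, px.
#' @param min_max_adhesion minimum peak wavelength shift, pm.
#' @param min_edge_distance minimum centroid distance from the well border,
#'   px; the default 4 guarantees the 8 x 8 crop fits inside the well.
#' @return filtered tibble, original order preserved.
#' @export
filter_candidates <- function(candidates, min_area = 1, max_area = Inf,
                              min_max_adhesion = 0, min_edge_distance = 4) {
  if (min_area > max_area) abort("`min_area` must not exceed `max_area`")
  if (min(min_area, min_max_adhesion, min_edge_distance) < 0) {
    abort("thresholds must be non-negative")
  }
  dplyr::filter(
    candidates,
    .data$area >= min_area, .data$area <= max_area,
    .data$max_adhesion >= min_max_adhesion,
    .data$edge_distance >= min_edge_distance
  )
}

#' Extract one (t, 8, 8) single-cell sample
#'
#' Crops rows `r - 3 ... r + 4` and columns `c - 3 ... c + 4` around the
#' candidate centroid (which lands at crop index (4, 4)), truncated to the
#' first `timespan_minutes` of the re-zeroed timeline. The full 8 x 8
#' neighborhood is kept; pixels outside the candidate's pixel set are not
#' zeroed.
#'
#' @param well a corrected, trimmed `well_video`.
#' @param candidate one row of a candidates tibble.
#' @param timespan_minutes sample duration; frames with re-zeroed timestamps
#'   `<= timespan_minutes * 60` are kept.
#' @param label optional cell-type label attached to the sample.
#' @return a one-row samples tibble: metadata plus a `video` list-column
#'   holding the `(t, 8, 8)` array.
#' @export
extract_sample <- function(well, candidate, timespan_minutes = 90, label = NA_character_) {
  stopifnot(inherits(well, "well_video"))
  r <- candidate$centroid_row[1]; c <- candidate$centroid_col[1]
  h <- dim(well$video)[2]; w <- dim(well$video)[3]
  if (r - 3 < 1 || r + 4 > h || c - 3 < 1 || c + 4 > w) {
    abort("centroid too close to the well border for an 8 x 8 crop")
  }
  keep_t <- which(well$timeline <= timespan_minutes * 60)
  vid <- well$video[keep_t, (r - 3):(r + 4), (c - 3):(c + 4), drop = FALSE]
  tibble(
    well_id = candidate$well_id[1], cell_id = candidate$cell_id[1],
    strategy = candidate$strategy[1], label = label,
    centroid_row = r, centroid_col = c,
    timespan_min = timespan_minutes,
    video = list(vid)
  )
}

#' Extract samples for every candidate of a well
#'
#' @param well a corrected `well_video`.
#' @param candidates candidates tibble (after [filter_candidates()]).
#' @param timespan_minutes sample duration in minutes.
#' @param labels optional character vector of per-candidate labels.
#' @return samples tibble, one row per candidate.
#' @export
extract_samples <- function(well, candidates, timespan_minutes = 90, labels = NULL) {
  if (nrow(candidates) == 0) return(extract_sample_empty())
  labels <- labels %||% rep(NA_character_, nrow(candidates))
  purrr::map2_dfr(seq_len(nrow(candidates)), labels, function(i, lb) {
    extract_sample(well, candidates[i, ], timespan_minutes, label = lb)
  })
}

extract_sample_empty <- function() {
  tibble(well_id = character(), cell_id = integer(), strategy = character(),
         label = character(), centroid_row = double(), centroid_col = double(),
         timespan_min = double(), video = list())
}

#' Export samples as multi-frame TIFFs with a manifest
#'
#' One TIFF per sample (picometer codec, see [write_ws_tiff()]); the
#' manifest CSV lists `path`, `label`, `well_id`, `cell_id`, `strategy`.
#'
#' @param samples samples tibble.
#' @param directory output directory (created if needed).
#' @return manifest tibble, invisibly; also written as `manifest.csv`.
#' @export
export_samples <- function(samples, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    paths[i] <- sprintf("sample_%s_%03d_%s.tiff",
                        samples$well_id[i], samples$cell_id[i], samples$strategy[i])
    write_ws_tiff(samples$video[[i]], file.path(directory, paths[i]))
  }
  manifest <- tibble(path = paths, label = samples$label,
                     well_id = samples$well_id, cell_id = samples$cell_id,
                     strategy = samples$strategy)
  readr::write_csv(manifest, file.path(directory, "manifest.csv"))
  invisible(manifest)
}

#' Read samples back from an export directory
#'
#' @param directory directory with `manifest.csv` and sample TIFFs.
#' @return samples tibble with a `video` list-column.
#' @export
read_samples <- function(directory) {
  manifest <- readr::read_csv(file.path(directory, "manifest.csv"),
                              show_col_types = FALSE)
  manifest$video <- lapply(manifest$path, function(p) read_ws_tiff(file.path(directory, p)))
  as_tibble(manifest)
}
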