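## Synthetic experiment generator.
##
## Emulates an Epic Cardio-style recording session: a (T, 240, 320)
## wavelength-shift mosaic covering 12 wells in a 3 x 4 arrangement at 25 um
## pitch, a timeline with a pipetting gap before the adhesion phase, and a
## paired phase-contrast microscope image + integer label mask per well,
## related to the biosensor plane by a known scale-plus-translation transform.
## Cell adhesion follows a saturating-exponential kinetic template
## A * (1 - exp(-k * t)) with an isotropic Gaussian spatial footprint whose
## 75 pm superlevel set spans roughly 3 x 3 biosensor pixels.

#' Configuration for a synthetic adhesion experiment
#'
#' Defaults describe a desk-scale recording: 6 wells of a 3 x 4 plate, 45
#' frames at 135 s (5 baseline frames, then a 1800 s pipetting gap, then 40
#' adhesion frames spanning 90 min), three cell types whose saturating
#' kinetics differ in amplitude and rate, 6 pm additive sensor noise and a
#' 0.2 pm/frame global drift. The microscope plane is 10x the biosensor
#' resolution (2.5 um vs 25 um pixels).
#'
#' @param n_wells number of populated wells (at most `prod(grid)`).
#' @param grid mosaic layout `(rows, cols)` of wells; the sensor mosaic is
#'   `80 * grid` pixels.
#' @param T_frames total frame count, baseline frames included.
#' @param frame_interval seconds between consecutive scans.
#' @param baseline_frames frames recorded before the pipetting gap.
#' @param n_cells_per_well cells seeded per populated well.
#' @param cell_types character vector of type names.
#' @param kinetics data frame with columns `type`, `amplitude` (pm),
#'   `rate` (1/min), `onset_jitter` (min); one row per cell type.
#' @param footprint_sigma isotropic Gaussian footprint width in biosensor
#'   pixels. The default 1.3 px puts the 75 pm superlevel set of a 150 pm
#'   cell on a 3 x 3 pixel block.
#' @param noise_sigma additive Gaussian sensor noise, pm.
#' @param drift amplitude of the global per-frame offset, pm: every adhesion
#'   frame carries one offset drawn uniformly from `[-drift, drift]`,
#'   emulating well-wide thermal/optical drift that background correction
#'   must remove.
#' @param true_scale microscope pixels per biosensor pixel (> 1).
#' @param true_translation length-2 `(row, col)` offset in microscope pixels.
#' @param pipette_gap seconds inserted into the timeline before the adhesion
#'   frames.
#' @param edge_artifact_density fraction of the well's 2-px border ring
#'   carrying a static resonance artifact (where the sensor meets the well
#'   boundary); 0 disables artifacts.
#' @param edge_artifact_amplitude artifact magnitude in pm; each artifact
#'   pixel holds a constant offset drawn from
#'   `[0.5, 1.5] * edge_artifact_amplitude` in every frame.
#' @param min_separation minimum centroid separation in biosensor px; cells
#'   violating it are resampled.
#' @param border_margin minimum centroid distance from the well border, px.
#' @param max_tries resampling attempts per cell before erroring.
#' @param seed RNG seed; identical configs produce bit-identical output.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_wells = 6,
                             grid = c(3, 4),
                             T_frames = 45,
                             frame_interval = 135,
                             baseline_frames = 5,
                             n_cells_per_well = 12,
                             cell_types = c("weak", "moderate", "strong"),
                             kinetics = NULL,
                             footprint_sigma = 1.3,
                             noise_sigma = 6,
                             drift = 5,
                             true_scale = 10,
                             true_translation = c(12.5, 8),
                             pipette_gap = 1800,
                             edge_artifact_density = 0.15,
                             edge_artifact_amplitude = 20000,
                             min_separation = 8,
                             border_margin = 5,
                             max_tries = 200,
                             seed = 1) {
  if (is.null(kinetics)) {
    kinetics <- tibble(
      type = cell_types,
      amplitude = seq(150, by = 150, length.out = length(cell_types)),
      rate = seq(0.04, by = 0.025, length.out = length(cell_types)),
      onset_jitter = rep(2, length(cell_types))
    )
  }
  kinetics <- as_tibble(kinetics)
  stopifnot(all(c("type", "amplitude", "rate", "onset_jitter") %in% names(kinetics)))
  if (!all(cell_types %in% kinetics$type)) {
    abort("every entry of `cell_types` needs a row in `kinetics`")
  }
  if (any(kinetics$amplitude <= 0) || any(kinetics$rate <= 0)) {
    abort("kinetic amplitudes and rates must be strictly positive")
  }
  stopifnot_scalar_number(footprint_sigma, "footprint_sigma", positive = TRUE)
  if (!is_count(n_cells_per_well)) abort("`n_cells_per_well` must be a non-negative integer")
  if (noise_sigma < 0) abort("`noise_sigma` must be non-negative")
  stopifnot_scalar_number(true_scale, "true_scale")
  if (true_scale <= 1) abort("`true_scale` must exceed 1 (microscope is the finer plane)")
  if (!is_count(n_wells) || n_wells > prod(grid)) {
    abort(sprintf("`n_wells` must be an integer between 0 and %d (grid overflow)", prod(grid)))
  }
  if (baseline_frames < 1 || baseline_frames >= T_frames) {
    abort("`baseline_frames` must be >= 1 and < `T_frames`")
  }
  structure(
    list(
      n_wells = as.integer(n_wells), grid = as.integer(grid),
      T_frames = as.integer(T_frames), frame_interval = frame_interval,
      baseline_frames = as.integer(baseline_frames),
      n_cells_per_well = as.integer(n_cells_per_well),
      cell_types = cell_types, kinetics = kinetics,
      footprint_sigma = footprint_sigma, noise_sigma = noise_sigma,
      drift = drift, true_scale = true_scale,
      true_translation = as.numeric(true_translation),
      pipette_gap = pipette_gap,
      edge_artifact_density = edge_artifact_density,
      edge_artifact_amplitude = edge_artifact_amplitude,
      min_separation = min_separation,
      border_margin = border_margin, max_tries = as.integer(max_tries),
      seed = seed
    ),
    class = "synthetic_config"
  )
}

# Gaussian footprint value at squared distance d2, unit peak.
footprint_gain <- function(d2, sigma) exp(-d2 / (2 * sigma^2))

# 75 pm footprint radius of a cell with asymptotic amplitude A (biosensor px).
footprint_radius <- function(amplitude, sigma, threshold = 75) {
  if (amplitude <= threshold) return(sigma)
  sigma * sqrt(2 * log(amplitude / threshold))
}

well_positions <- function(grid, n_wells) {
  pos <- expand.grid(col = seq_len(grid[2]), row = seq_len(grid[1]))[, c("row", "col")]
  pos <- pos[seq_len(n_wells), , drop = FALSE]
  tibble(well_id = sprintf("%s%d", LETTERS[pos$row], pos$col),
         grid_row = pos$row, grid_col = pos$col)
}

#' Generate a complete synthetic experiment
#'
#' Produces the raw biosensor mosaic with its timeline, one phase-contrast
#' style microscope image and ground-truth label mask per populated well, and
#' a ground-truth table with per-cell kinetic parameters, centroids on both
#' planes and footprint pixel sets. All randomness is governed by
#' `config$seed`; identical configs yield bit-identical output.
#'
#' Per-cell signal at biosensor pixel p and post-onset time t (minutes) is
#' `A * (1 - exp(-k * t)) * exp(-d(p, centroid)^2 / (2 * sigma^2))`; baseline
#' frames (before the pipetting gap) carry only noise. The mosaic is
#' quantized to the instrument's 0.25 pm scan step.
#'
#' @param config a [synthetic_config()].
#' @return a list of class `synthetic_experiment` with elements `video`
#'   (`(T, 240, 320)` pm array), `timeline` (seconds), `wells` (well layout
#'   tibble), `microscope` (named list of grayscale images), `masks` (named
#'   list of [label_mask()] objects) and `ground_truth` (list with `cells`
#'   tibble, `transform`, `adhesion_start_index`).
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_experiment_impl(config))
}

generate_experiment_impl <- function(cfg) {
  n_adh <- cfg$T_frames - cfg$baseline_frames
  base_t <- (seq_len(cfg$baseline_frames) - 1) * cfg$frame_interval
  t_start <- base_t[cfg$baseline_frames] + cfg$pipette_gap
  adh_t <- t_start + (seq_len(n_adh) - 1) * cfg$frame_interval
  timeline <- c(base_t, adh_t)
  start_index <- cfg$baseline_frames + 1L

  mosaic_dim <- c(cfg$T_frames, 80L * cfg$grid[1], 80L * cfg$grid[2])
  wells <- well_positions(cfg$grid, cfg$n_wells)
  tf <- projection_transform(cfg$true_scale, cfg$true_translation)

  # microscope canvas large enough for the projected sensor plus margin
  m_dim <- ceiling(cfg$true_scale * 80.5 + pmax(cfg$true_translation, 0)) + 2

  signal <- array(0, mosaic_dim)        # clean field, for ground truth
  artifact <- matrix(0, mosaic_dim[2], mosaic_dim[3])  # static sensor defects
  cells_rows <- list()
  microscope <- list()
  masks <- list()

  for (w in seq_len(nrow(wells))) {
    wid <- wells$well_id[w]
    r0 <- (wells$grid_row[w] - 1) * 80
    c0 <- (wells$grid_col[w] - 1) * 80

    cents <- sample_centroids(cfg)
    n_cells <- nrow(cents)
    types <- if (n_cells > 0) {
      sample(rep(cfg$cell_types, length.out = n_cells))
    } else {
      character(0)
    }

    m_img <- matrix(0, m_dim[1], m_dim[2])
    m_mask <- matrix(0L, m_dim[1], m_dim[2])
    grid_r <- matrix(seq_len(80), 80, 80)
    grid_c <- matrix(seq_len(80), 80, 80, byrow = TRUE)
    mr <- matrix(seq_len(m_dim[1]), m_dim[1], m_dim[2])
    mc <- matrix(seq_len(m_dim[2]), m_dim[1], m_dim[2], byrow = TRUE)

    for (i in seq_len(n_cells)) {
      kin <- cfg$kinetics[cfg$kinetics$type == types[i], ]
      onset_min <- runif(1, 0, kin$onset_jitter)
      cb <- as.numeric(cents[i, ])
      cm <- cfg$true_scale * cb + cfg$true_translation

      d2 <- (grid_r - cb[1])^2 + (grid_c - cb[2])^2
      gain <- footprint_gain(d2, cfg$footprint_sigma)
      elapsed <- pmax((adh_t - t_start) / 60 - onset_min, 0)
      amp_t <- kin$amplitude * (1 - exp(-kin$rate * elapsed))
      for (j in seq_len(n_adh)) {
        t_idx <- cfg$baseline_frames + j
        signal[t_idx, r0 + seq_len(80), c0 + seq_len(80)] <-
          signal[t_idx, r0 + seq_len(80), c0 + seq_len(80)] + amp_t[j] * gain
      }

      # microscope ellipse: footprint radius scaled to the microscope plane,
      # with mild axis jitter (cell shape is not perfectly round)
      rb <- footprint_radius(kin$amplitude, cfg$footprint_sigma)
      ax <- cfg$true_scale * rb * runif(1, 0.9, 1.1)
      bx <- cfg$true_scale * rb * runif(1, 0.9, 1.1)
      inside <- ((mr - cm[1]) / ax)^2 + ((mc - cm[2]) / bx)^2 <= 1
      m_mask[inside] <- i
      m_img[inside] <- m_img[inside] + 0.45

      cells_rows[[length(cells_rows) + 1L]] <- tibble(
        well_id = wid, cell_id = i, type = types[i],
        centroid_b_row = cb[1], centroid_b_col = cb[2],
        centroid_m_row = cm[1], centroid_m_col = cm[2],
        amplitude = kin$amplitude, rate = kin$rate, onset_min = onset_min
      )
    }

    # static boundary artifacts on the well's outer 2-px ring
    if (cfg$edge_artifact_density > 0 && cfg$edge_artifact_amplitude > 0) {
      ring <- which(outer(seq_len(80), seq_len(80), function(r, c) {
        pmin(r - 1, c - 1, 80 - r, 80 - c) < 2
      }))
      n_art <- round(cfg$edge_artifact_density * length(ring))
      if (n_art > 0) {
        art_px <- sample(ring, n_art)
        vals <- cfg$edge_artifact_amplitude * runif(n_art, 0.5, 1.5)
        wf <- matrix(0, 80, 80)
        wf[art_px] <- vals
        artifact[r0 + seq_len(80), c0 + seq_len(80)] <- wf
      }
    }

    m_img <- m_img + 0.25 + matrix(rnorm(prod(m_dim), 0, 0.02), m_dim[1], m_dim[2])
    m_img <- pmin(pmax(m_img, 0), 1)
    m_img <- round(m_img * 65535) / 65535     # 16-bit storage grid
    microscope[[wid]] <- m_img
    masks[[wid]] <- label_mask(m_mask, pixel_size = 25 / cfg$true_scale)
  }

  cells <- if (length(cells_rows)) dplyr::bind_rows(cells_rows) else tibble(
    well_id = character(), cell_id = integer(), type = character(),
    centroid_b_row = double(), centroid_b_col = double(),
    centroid_m_row = double(), centroid_m_col = double(),
    amplitude = double(), rate = double(), onset_min = double()
  )

  # footprint (75 pm superlevel of the final clean frame) and mask-cover
  # pixel sets on the biosensor plane, by brute-force enumeration
  if (nrow(cells) > 0) {
    cells$footprint_b <- vector("list", nrow(cells))
    cells$cover_b <- vector("list", nrow(cells))
    for (idx in seq_len(nrow(cells))) {
      wrow <- wells[wells$well_id == cells$well_id[idx], ]
      cb <- c(cells$centroid_b_row[idx], cells$centroid_b_col[idx])
      kin <- cells[idx, ]
      final_elapsed <- (adh_t[n_adh] - t_start) / 60 - kin$onset_min
      px <- expand.grid(row = seq_len(80), col = seq_len(80))
      d2 <- (px$row - cb[1])^2 + (px$col - cb[2])^2
      val <- kin$amplitude * (1 - exp(-kin$rate * final_elapsed)) *
        footprint_gain(d2, cfg$footprint_sigma)
      cells$footprint_b[[idx]] <- as.matrix(px[val >= 75, , drop = FALSE])
      mpx <- which(masks[[cells$well_id[idx]]]$labels == cells$cell_id[idx], arr.ind = TRUE)
      bpx <- unique(round((mpx - matrix(cfg$true_translation, nrow(mpx), 2, byrow = TRUE)) /
                            cfg$true_scale))
      keep <- bpx[, 1] >= 1 & bpx[, 1] <= 80 & bpx[, 2] >= 1 & bpx[, 2] <= 80
      cover <- bpx[keep, , drop = FALSE]
      colnames(cover) <- c("row", "col")
      cells$cover_b[[idx]] <- cover
    }
  }

  noise <- if (cfg$noise_sigma > 0) {
    array(rnorm(prod(mosaic_dim), 0, cfg$noise_sigma), mosaic_dim)
  } else {
    array(0, mosaic_dim)
  }
  drift_off <- c(rep(0, cfg$baseline_frames), runif(n_adh, -cfg$drift, cfg$drift))
  video <- signal + noise +
    array(rep(drift_off, times = prod(mosaic_dim[2:3])), mosaic_dim)
  for (t in seq_len(mosaic_dim[1])) video[t, , ] <- video[t, , ] + artifact
  video <- round(video / 0.25) * 0.25        # instrument scan-step quantization

  structure(
    list(
      video = video, timeline = timeline, wells = wells,
      microscope = microscope, masks = masks,
      ground_truth = list(cells = cells, transform = tf,
                          adhesion_start_index = start_index),
      config = cfg
    ),
    class = "synthetic_experiment"
  )
}

sample_centroids <- function(cfg) {
  lo <- cfg$border_margin + 1
  hi <- 80 - cfg$border_margin
  pts <- matrix(numeric(0), 0, 2)
  for (i in seq_len(cfg$n_cells_per_well)) {
    ok <- FALSE
    for (try in seq_len(cfg$max_tries)) {
      cand <- c(sample(lo:hi, 1), sample(lo:hi, 1))
      if (nrow(pts) == 0 ||
          min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >= cfg$min_separation) {
        pts <- rbind(pts, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort(sprintf(
        "could not place %d cells with min_separation = %g after %d tries",
        cfg$n_cells_per_well, cfg$min_separation, cfg$max_tries))
    }
  }
  colnames(pts) <- c("row", "col")
  as.data.frame(pts)
}

#' Simulate labelled (t, 8, 8) single-cell samples directly
#'
#' A sample-level shortcut around the full experiment generator: each sample
#' is one cell centered in its 8 x 8 crop (centroid at index (4, 4)), with
#' the same saturating kinetic template, Gaussian footprint, onset jitter and
#' sensor noise as [generate_experiment()]. Useful for classifier studies
#' where segmentation is not under test.
#'
#' @param n_per_type samples per cell type.
#' @param T_frames frames per sample.
#' @param frame_interval seconds per frame.
#' @param kinetics data frame with `type`, `amplitude`, `rate`,
#'   `onset_jitter` columns as in [synthetic_config()].
#' @param footprint_sigma,noise_sigma as in [synthetic_config()].
#' @param amplitude_cv per-cell coefficient of variation of the amplitude
#'   (biological variability between cells of one type).
#' @param seed RNG seed.
#' @return a samples tibble: `sample_id`, `label`, and a `video` list-column
#'   of `(T, 8, 8)` pm arrays.
#' @export
simulate_samples <- function(n_per_type = 200, T_frames = 40, frame_interval = 135,
                             kinetics = NULL, footprint_sigma = 1.3,
                             noise_sigma = 6, amplitude_cv = 0.05, seed = 1) {
  if (is.null(kinetics)) kinetics <- synthetic_config()$kinetics
  kinetics <- as_tibble(kinetics)
  with_seed(seed, {
    rows <- list()
    sid <- 0L
    grid_r <- matrix(seq_len(8), 8, 8)
    grid_c <- matrix(seq_len(8), 8, 8, byrow = TRUE)
    d2 <- (grid_r - 4)^2 + (grid_c - 4)^2
    gain <- footprint_gain(d2, footprint_sigma)
    tmin <- (seq_len(T_frames) - 1) * frame_interval / 60
    for (k in seq_len(nrow(kinetics))) {
      kin <- kinetics[k, ]
      for (i in seq_len(n_per_type)) {
        sid <- sid + 1L
        amp <- kin$amplitude * max(rnorm(1, 1, amplitude_cv), 0.2)
        onset <- runif(1, 0, kin$onset_jitter)
        amp_t <- amp * (1 - exp(-kin$rate * pmax(tmin - onset, 0)))
        vid <- outer(amp_t, gain) # (T, 64)
        dim(vid) <- c(T_frames, 8, 8)
        if (noise_sigma > 0) {
          vid <- vid + array(rnorm(T_frames * 64, 0, noise_sigma), c(T_frames, 8, 8))
        }
        rows[[sid]] <- tibble(sample_id = sid, label = kin$type, video = list(vid))
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Write a synthetic experiment to disk
#'
#' Lays an experiment out the way the pipeline expects instrument exports:
#' `mosaic.tiff` (multi-frame wavelength-shift video), `timeline.csv`,
#' `microscope_<well>.tiff` / `mask_<well>.tiff` per populated well,
#' `ground_truth.csv`, `ground_truth_pixels.csv` (long table of footprint and
#' cover pixel sets) and `transform.json`. All rasters round-trip bit-exactly
#' through [read_experiment()].
#'
#' @param experiment a `synthetic_experiment` from [generate_experiment()].
#' @param directory output directory, created if missing.
#' @return a manifest tibble (`file`, `kind`, `well_id`), invisibly.
#' @export
write_experiment <- function(experiment, directory) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  man <- list()
  add <- function(file, kind, well_id = NA_character_) {
    man[[length(man) + 1L]] <<- tibble(file = file, kind = kind, well_id = well_id)
  }

  write_ws_tiff(experiment$video, file.path(directory, "mosaic.tiff"))
  add("mosaic.tiff", "mosaic")
  write_timeline_csv(experiment$timeline, file.path(directory, "timeline.csv"))
  add("timeline.csv", "timeline")

  for (wid in names(experiment$masks)) {
    mf <- sprintf("microscope_%s.tiff", wid)
    kf <- sprintf("mask_%s.tiff", wid)
    tiff::writeTIFF(experiment$microscope[[wid]], file.path(directory, mf),
                    bits.per.sample = 16L, compression = "none", reduce = FALSE)
    write_mask(experiment$masks[[wid]], file.path(directory, kf))
    add(mf, "microscope", wid)
    add(kf, "mask", wid)
  }

  gt <- experiment$ground_truth
  flat <- gt$cells
  flat$footprint_b <- NULL
  flat$cover_b <- NULL
  readr::write_csv(flat, file.path(directory, "ground_truth.csv"))
  add("ground_truth.csv", "ground_truth")

  px <- pixel_sets_long(gt$cells)
  readr::write_csv(px, file.path(directory, "ground_truth_pixels.csv"))
  add("ground_truth_pixels.csv", "ground_truth_pixels")

  write_transform(gt$transform, file.path(directory, "transform.json"),
                  extra = list(adhesion_start_index = gt$adhesion_start_index))
  add("transform.json", "transform")

  manifest <- dplyr::bind_rows(man)
  readr::write_csv(manifest, file.path(directory, "manifest.csv"))
  invisible(manifest)
}

pixel_sets_long <- function(cells) {
  if (nrow(cells) == 0 || is.null(cells$footprint_b)) {
    return(tibble(well_id = character(), cell_id = integer(), kind = character(),
                  row = integer(), col = integer()))
  }
  out <- list()
  for (i in seq_len(nrow(cells))) {
    for (kind in c("footprint_b", "cover_b")) {
      px <- cells[[kind]][[i]]
      if (NROW(px) > 0) {
        out[[length(out) + 1L]] <- tibble(
          well_id = cells$well_id[i], cell_id = cells$cell_id[i],
          kind = sub("_b$", "", kind),
          row = as.integer(px[, 1]), col = as.integer(px[, 2])
        )
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble(well_id = character(), cell_id = integer(), kind = character(),
           row = integer(), col = integer())
}

#' Read back an experiment written by [write_experiment()]
#'
#' @param directory directory containing a `manifest.csv`.
#' @return a list with `video`, `timeline`, `microscope`, `masks`,
#'   `ground_truth` mirroring [generate_experiment()] output (pixel-set
#'   list-columns are restored from the long table).
#' @export
read_experiment <- function(directory) {
  manifest <- readr::read_csv(file.path(directory, "manifest.csv"),
                              show_col_types = FALSE)
  video <- read_ws_tiff(file.path(directory, "mosaic.tiff"))
  timeline <- read_timeline_csv(file.path(directory, "timeline.csv"))
  wids <- manifest$well_id[manifest$kind == "mask"]
  microscope <- list()
  masks <- list()
  for (wid in wids) {
    microscope[[wid]] <- tiff::readTIFF(
      file.path(directory, sprintf("microscope_%s.tiff", wid)))
    masks[[wid]] <- read_mask(file.path(directory, sprintf("mask_%s.tiff", wid)))
  }
  cells <- readr::read_csv(file.path(directory, "ground_truth.csv"),
                           show_col_types = FALSE)
  px <- readr::read_csv(file.path(directory, "ground_truth_pixels.csv"),
                        show_col_types = FALSE)
  if (nrow(cells) > 0) {
    cells$footprint_b <- vector("list", nrow(cells))
    cells$cover_b <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      for (kind in c("footprint", "cover")) {
        sel <- px[px$well_id == cells$well_id[i] & px$cell_id == cells$cell_id[i] &
                    px$kind == kind, c("row", "col")]
        cells[[paste0(kind, "_b")]][[i]] <- as.matrix(sel)
      }
    }
  }
  tf <- read_transform(file.path(directory, "transform.json"))
  list(video = video, timeline = timeline, microscope = microscope,
       masks = masks,
       ground_truth = list(cells = cells, transform = tf$transform,
                           adhesion_start_index = tf$extra$adhesion_start_index))
}
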