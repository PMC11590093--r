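# Shared fixture builders. Everything is generated in code; no binary
# fixtures on disk.

# a small, fast experiment configuration
tiny_config <- function(...) {
  defaults <- list(n_wells = 1, T_frames = 15, baseline_frames = 3,
                   n_cells_per_well = 4, min_separation = 12, seed = 101)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

# build a well_video directly from an array (bypassing the mosaic)
make_well <- function(video, timeline = NULL, well_id = "A1") {
  timeline <- timeline %||% ((seq_len(dim(video)[1]) - 1) * 3)
  adhekin:::new_well_video(video, timeline = timeline, well_id = well_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a corrected well with known content: zeros everywhere except optional
# gaussian cells; runs offset correction so raw_first is present
make_corrected_well <- function(T = 10, cells = NULL, noise = 0, seed = 1) {
  set.seed(seed)
  v <- array(if (noise > 0) rnorm(T * 80 * 80, 0, noise) else 0, c(T, 80, 80))
  if (!is.null(cells)) {
    gr <- matrix(seq_len(80), 80, 80)
    gc <- matrix(seq_len(80), 80, 80, byrow = TRUE)
    for (i in seq_len(nrow(cells))) {
      d2 <- (gr - cells$row[i])^2 + (gc - cells$col[i])^2
      g <- cells$amp[i] * exp(-d2 / (2 * 1.3^2))
      ramp <- seq(0, 1, length.out = T)
      for (t in seq_len(T)) v[t, , ] <- v[t, , ] + ramp[t] * g
    }
  }
  offset_correct(make_well(v))
}

# per-frame mean over a well's selected background pixels
apply_bg_mean <- function(w) {
  flat <- (w$background_pixels[, 2] - 1) * dim(w$video)[2] + w$background_pixels[, 1]
  vm <- matrix(w$video, dim(w$video)[1], prod(dim(w$video)[2:3]))
  rowMeans(vm[, flat, drop = FALSE])
}

# deterministic labelled samples for classifier tests: type signal is a
# separable mean level
make_toy_samples <- function(n_per_class = 12, T = 8, classes = c("a", "b"),
                             gap = 8, noise = 1, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_along(classes), function(k) {
    lapply(seq_len(n_per_class), function(i) {
      v <- array(rnorm(T * 64, mean = k * gap, sd = noise), c(T, 8, 8))
      tibble::tibble(label = classes[k], video = list(v))
    })
  })
  dplyr::bind_rows(unlist(rows, recursive = FALSE))
}
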