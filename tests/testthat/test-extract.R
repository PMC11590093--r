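test_that("local maxima search matches a brute-force neighborhood scan", {
  expect_equal(nrow(find_local_maxima(matrix(5, 20, 20), lower_threshold = 1)), 0)
  # two gaussians 10 px apart
  gr <- matrix(seq_len(30), 30, 30); gc <- t(gr)
  img <- 200 * exp(-((gr - 10)^2 + (gc - 15)^2) / 4) +
    150 * exp(-((gr - 20)^2 + (gc - 15)^2) / 4)
  mx <- find_local_maxima(img, min_distance = 3)
  expect_equal(nrow(mx), 2)
  expect_setequal(paste(mx[, 1], mx[, 2]), c("10 15", "20 15"))
  # random images vs exhaustive scan
  set.seed(14)
  for (i in 1:5) {
    im <- matrix(runif(400, 0, 200), 20, 20)
    mx <- find_local_maxima(im, lower_threshold = 50, upper_threshold = 180,
                            min_distance = 2)
    brute <- list()
    for (r in 1:20) for (cc in 1:20) {
      v <- im[r, cc]
      if (v < 50 || v > 180) next
      nb <- im[max(1, r - 2):min(20, r + 2), max(1, cc - 2):min(20, cc + 2)]
      if (v == max(nb) && sum(nb == v) == 1) {
        brute[[length(brute) + 1]] <- c(r, cc)
      }
    }
    brute <- do.call(rbind, brute)
    expect_setequal(paste(mx[, 1], mx[, 2]), paste(brute[, 1], brute[, 2]))
  }
})

test_that("watershed partitions the foreground one region per seed", {
  # one blob, one seed
  gr <- matrix(seq_len(40), 40, 40); gc <- t(gr)
  img <- 200 * exp(-((gr - 20)^2 + (gc - 20)^2) / 18)
  seeds <- find_local_maxima(img)
  ws <- watershed_segment(img, seeds)
  fg <- img >= 75
  expect_equal(sort(unique(as.vector(ws$labels[fg]))), 1L)
  expect_true(all(ws$labels[!fg] == 0L))
  # symmetric dumbbell splits at the neck midline
  img2 <- 200 * exp(-((gr - 14)^2 + (gc - 20)^2) / 10) +
    200 * exp(-((gr - 26)^2 + (gc - 20)^2) / 10)
  seeds2 <- find_local_maxima(img2, min_distance = 3)
  expect_equal(nrow(seeds2), 2)
  ws2 <- watershed_segment(img2, seeds2)
  fg2 <- img2 >= 75
  expect_setequal(unique(as.vector(ws2$labels[fg2])), c(1L, 2L))
  expect_true(all(ws2$labels[fg2] > 0))  # regions partition the foreground
  # rows < 20 belong to seed 1, rows > 20 to seed 2 (symmetry)
  lab_top <- ws2$labels[1:19, ][fg2[1:19, ]]
  lab_bot <- ws2$labels[21:40, ][fg2[21:40, ]]
  expect_true(all(lab_top == 1L))
  expect_true(all(lab_bot == 2L))
  # no seeds: empty mask
  expect_equal(n_cells(watershed_segment(img, matrix(numeric(0), 0, 2))), 0)
})

test_that("region count equals seed count on synthetic wells", {
  e <- generate_experiment(tiny_config(noise_sigma = 0, drift = 0))
  w <- preprocess_recording(e$video, e$timeline, wells = "A1")$A1
  ki <- kinetic_image(w)
  seeds <- find_local_maxima(ki)
  ws <- watershed_segment(ki, seeds)
  expect_equal(n_cells(ws), nrow(seeds))
  expect_equal(nrow(seeds), sum(e$ground_truth$cells$well_id == "A1"))
})

test_that("candidates carry brute-force-checked properties", {
  w <- make_corrected_well(T = 6, cells = data.frame(row = c(20, 50), col = c(20, 60),
                                                     amp = c(200, 300)))
  expect_equal(nrow(build_candidates(w, list())), 0)
  ki <- kinetic_image(w)
  ws <- watershed_segment(ki, find_local_maxima(ki))
  cand <- build_candidates(w, ws, "W")
  expect_equal(nrow(cand), 2)
  for (i in 1:2) {
    px <- cand$pixel_set[[i]]
    vals <- apply(px, 1, function(p) max(w$video[, p[1], p[2]]))
    expect_equal(cand$max_adhesion[i], max(vals))
    expect_equal(cand$area[i], nrow(px))
    ctr <- round(colMeans(px))
    expect_equal(c(cand$centroid_row[i], cand$centroid_col[i]), unname(ctr))
  }
})

test_that("candidate filtering equals brute-force predicate evaluation", {
  w <- make_corrected_well(T = 6, cells = data.frame(
    row = c(5, 20, 40, 76), col = c(5, 20, 40, 2), amp = c(100, 200, 300, 250)))
  ki <- kinetic_image(w)
  cand <- build_candidates(w, watershed_segment(ki, find_local_maxima(ki)), "W")
  expect_identical(filter_candidates(cand, 1, Inf, 0, 0), cand)
  f <- filter_candidates(cand, min_area = 3, max_area = 40,
                         min_max_adhesion = 150, min_edge_distance = 4)
  keep <- cand$area >= 3 & cand$area <= 40 & cand$max_adhesion >= 150 &
    cand$edge_distance >= 4
  expect_equal(f$cell_id, cand$cell_id[keep])
  # an edge centroid is removed by the distance filter
  expect_false(any(f$centroid_col <= 4))
  expect_error(filter_candidates(cand, min_area = 10, max_area = 5), "exceed")
})

test_that("sample extraction crops exactly and prefixes nest", {
  set.seed(15)
  v <- array(rnorm(40 * 80 * 80), c(40, 80, 80))
  tl <- (seq_len(40) - 1) * 135
  w <- make_well(v, timeline = tl)
  cand <- tibble::tibble(well_id = "A1", cell_id = 1L, strategy = "M",
                         centroid_row = 4, centroid_col = 4)
  s <- extract_sample(w, cand, timespan_minutes = 90)
  expect_identical(s$video[[1]], v[, 1:8, 1:8])  # corner case: crop starts at 1
  # random centroids against a slicing oracle
  for (i in 1:5) {
    r <- sample(5:75, 1); cc <- sample(5:75, 1)
    ci <- tibble::tibble(well_id = "A1", cell_id = i, strategy = "W",
                         centroid_row = r, centroid_col = cc)
    si <- extract_sample(w, ci, 90)
    expect_identical(si$video[[1]], v[, (r - 3):(r + 4), (cc - 3):(cc + 4)])
    expect_equal(dim(si$video[[1]])[2:3], c(8, 8))
  }
  # 30/60/90 minute samples are prefixes of each other
  s30 <- extract_sample(w, cand, 30)$video[[1]]
  s60 <- extract_sample(w, cand, 60)$video[[1]]
  s90 <- extract_sample(w, cand, 90)$video[[1]]
  expect_identical(s30, s60[seq_len(dim(s30)[1]), , , drop = FALSE])
  expect_identical(s60, s90[seq_len(dim(s60)[1]), , , drop = FALSE])
  expect_lt(dim(s30)[1], dim(s60)[1])
  # too close to the border
  bad <- tibble::tibble(well_id = "A1", cell_id = 9L, strategy = "M",
                        centroid_row = 2, centroid_col = 40)
  expect_error(extract_sample(w, bad, 30), "border")
})

test_that("exported samples round-trip with a faithful manifest", {
  e <- generate_experiment(tiny_config(noise_sigma = 0, drift = 0))
  w <- preprocess_recording(e$video, e$timeline, wells = "A1")$A1
  gt <- e$ground_truth$cells
  proj <- project_mask_to_biosensor(e$masks$A1, e$ground_truth$transform)
  cand <- filter_candidates(build_candidates(w, proj, "M"))
  labels <- gt$type[match(cand$cell_id, gt$cell_id)]
  samples <- extract_samples(w, cand, 90, labels = labels)
  dir <- withr::local_tempdir()
  manifest <- export_samples(samples, dir)
  expect_equal(nrow(manifest), nrow(samples))
  back <- read_samples(dir)
  for (i in seq_len(nrow(back))) {
    # corrected values land within half a codec quantum on first write and
    # are stable thereafter
    expect_lt(max(abs(back$video[[i]] - samples$video[[i]])), 2^-13 + 1e-12)
    f2 <- withr::local_tempfile(fileext = ".tiff")
    write_ws_tiff(back$video[[i]], f2)
    expect_identical(read_ws_tiff(f2), back$video[[i]])
  }
  expect_equal(back$label, gt$type[match(back$cell_id, gt$cell_id)])
})
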