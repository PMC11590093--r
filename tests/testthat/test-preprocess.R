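test_that("split_wells slices the mosaic by index arithmetic", {
  T <- 3
  mosaic <- array(0, c(T, 240, 320))
  # encode (row, col) into the pixel value
  for (r in 1:240) for (cc in 1:320) mosaic[, r, cc] <- r * 1000 + cc
  tl <- (0:(T - 1)) * 3
  wells <- split_wells(mosaic, tl)
  expect_length(wells, 12)
  expect_equal(dim(wells$A1$video), c(T, 80, 80))
  # brute-force corner checks for every well
  for (i in 1:3) for (j in 1:4) {
    w <- wells[[sprintf("%s%d", LETTERS[i], j)]]
    expect_equal(w$video[1, 1, 1], ((i - 1) * 80 + 1) * 1000 + ((j - 1) * 80 + 1))
    expect_equal(w$video[1, 80, 80], (i * 80) * 1000 + j * 80)
  }
  # constant mosaic stays constant
  wc <- split_wells(array(7, c(2, 240, 320)), c(0, 3))
  expect_true(all(vapply(wc, function(w) all(w$video == 7), logical(1))))
  expect_error(split_wells(array(0, c(2, 100, 320)), c(0, 3)), "mosaic")
})

test_that("adhesion start is the frame after the largest qualifying gap", {
  tl <- cumsum(c(0, rep(3, 38), 600, rep(3, 20))[-1])
  tl <- c(0, tl)
  expect_equal(detect_adhesion_start(tl), 40)
  expect_error(detect_adhesion_start(seq(0, 300, by = 3)), "gap")
  # two gaps: index after the larger one
  tl2 <- c(0, 3, 6, 106, 109, 112, 612, 615, 618)
  expect_equal(detect_adhesion_start(tl2), 7)
})

test_that("offset correction equals per-pixel first-frame subtraction", {
  set.seed(5)
  v <- array(rnorm(6 * 10 * 10), c(6, 10, 10))
  w <- offset_correct(make_well(v))
  expect_true(all(w$video[1, , ] == 0))
  for (t in 1:6) expect_equal(w$video[t, , ], v[t, , ] - v[1, , ])
  # constant-in-time video becomes all zeros
  vc <- array(rep(matrix(rnorm(100), 10), each = 6), c(6, 10, 10))
  for (t in 1:6) vc[t, , ] <- vc[1, , ]
  expect_true(all(offset_correct(make_well(vc))$video == 0))
})

test_that("outlier masking flags extreme raw pixels and is monotone in k", {
  # uniform raw frame: degenerate sd, nothing masked
  w <- offset_correct(make_well(array(5, c(4, 80, 80))))
  expect_equal(sum(mask_outliers(w)$outlier_mask), 0)
  # one enormous pixel among zeros
  v <- array(0, c(4, 80, 80))
  v[, 10, 10] <- 1e6
  w2 <- mask_outliers(offset_correct(make_well(v)))
  expect_true(w2$outlier_mask[10, 10])
  expect_equal(sum(w2$outlier_mask), 1)
  # mask at k = 3 contains mask at k = 4
  set.seed(6)
  v3 <- array(rnorm(4 * 80 * 80, 0, 10), c(4, 80, 80))
  v3[, 3, 3] <- 5e4
  w3 <- offset_correct(make_well(v3))
  m3 <- mask_outliers(w3, k = 3)$outlier_mask
  m4 <- mask_outliers(w3, k = 4)$outlier_mask
  expect_true(all(m3[m4]))
})

test_that("background selection respects threshold, distances and seed", {
  w <- make_corrected_well(T = 5)
  sel <- select_background_pixels(w, n = 50, min_dist_bg = 3, seed = 9)
  px <- sel$background_pixels
  expect_equal(nrow(px), 50)
  d <- as.matrix(dist(px))
  diag(d) <- Inf
  expect_gte(min(d), 3)
  # determinism and seed sensitivity
  sel2 <- select_background_pixels(w, n = 50, min_dist_bg = 3, seed = 9)
  expect_identical(sel2$background_pixels, px)
  sel3 <- select_background_pixels(w, n = 50, min_dist_bg = 3, seed = 10)
  expect_false(identical(sel3$background_pixels, px))

  # every selected pixel is below the 75 pm threshold and far from foreground
  wc <- make_corrected_well(T = 5, cells = data.frame(row = 40, col = 40, amp = 300))
  ref <- kinetic_image(wc)
  selc <- select_background_pixels(wc, n = 40, min_dist_fg = 2, seed = 1)
  vals <- ref[selc$background_pixels]
  expect_true(all(abs(vals) < 75))
  fg <- which(ref >= 75, arr.ind = TRUE)
  dfg <- adhekin:::cross_dist(selc$background_pixels, fg)
  expect_gte(min(dfg), 2)
})

test_that("confluent wells abort background selection", {
  v <- array(0, c(3, 80, 80))
  v[2, , ] <- 100  # everything above threshold
  w <- offset_correct(make_well(v))
  expect_error(select_background_pixels(w), "confluent")
})

test_that("background correction removes per-frame offsets exactly", {
  w <- make_corrected_well(T = 6, cells = data.frame(row = 30, col = 30, amp = 200))
  w <- select_background_pixels(w, n = 60, seed = 2)
  shifted <- w
  shifted$video <- w$video + 5  # constant +5 pm per frame
  corr <- correct_background(shifted)
  expect_equal(corr$video, sweep(w$video, 1, apply_bg_mean(w), "-"), tolerance = 1e-12)
  # per-frame background mean is zero after correction
  bgm <- apply_bg_mean(corr)
  expect_lt(max(abs(bgm)), 1e-6)
  # foreground - background contrast is unchanged
  fg_px <- c(30, 30); bg_px <- corr$background_pixels[1, ]
  before <- shifted$video[, fg_px[1], fg_px[2]] - shifted$video[, bg_px[1], bg_px[2]]
  after <- corr$video[, fg_px[1], fg_px[2]] - corr$video[, bg_px[1], bg_px[2]]
  expect_equal(after, before, tolerance = 1e-12)
  expect_error(correct_background(make_well(array(0, c(2, 80, 80)))), "background")
})

test_that("the full preprocessing pipeline is deterministic given a seed", {
  e <- generate_experiment(tiny_config())
  w1 <- preprocess_recording(e$video, e$timeline, wells = "A1", seed = 3)$A1
  w2 <- preprocess_recording(e$video, e$timeline, wells = "A1", seed = 3)$A1
  expect_identical(w1$video, w2$video)
  expect_identical(w1$background_pixels, w2$background_pixels)
  expect_identical(w1$outlier_mask, w2$outlier_mask)
})
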