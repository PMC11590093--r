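test_that("transform estimation is exact on constructed correspondences", {
  b <- cbind(c(10, 40, 70, 25), c(12, 60, 30, 45))
  m <- 2 * b + matrix(c(10, 5), 4, 2, byrow = TRUE)
  pairs <- data.frame(m_row = m[, 1], m_col = m[, 2], b_row = b[, 1], b_col = b[, 2])
  tf <- estimate_transform(pairs)
  expect_equal(tf$scale, 2, tolerance = 1e-9)
  expect_equal(tf$translation, c(10, 5), tolerance = 1e-9)
  # identity correspondence
  pid <- data.frame(m_row = b[, 1], m_col = b[, 2], b_row = b[, 1], b_col = b[, 2])
  tid <- estimate_transform(pid)
  expect_equal(tid$scale, 1, tolerance = 1e-12)
  expect_equal(tid$translation, c(0, 0), tolerance = 1e-12)
})

test_that("random noise-free transforms are recovered to 1e-9", {
  set.seed(11)
  for (i in 1:25) {
    s <- runif(1, 2, 40)
    tr <- runif(2, -50, 50)
    n <- sample(2:6, 1)
    b <- cbind(runif(n, 1, 80), runif(n, 1, 80))
    m <- s * b + matrix(tr, n, 2, byrow = TRUE)
    tf <- estimate_transform(data.frame(m_row = m[, 1], m_col = m[, 2],
                                        b_row = b[, 1], b_col = b[, 2]))
    expect_lt(abs(tf$scale - s), 1e-9)
    expect_lt(max(abs(tf$translation - tr)), 1e-9)
  }
})

test_that("a single pair estimates translation with the nominal scale", {
  pairs <- data.frame(m_row = 110, m_col = 58, b_row = 10, b_col = 5)
  tf <- estimate_transform(pairs, nominal_scale = 10)
  expect_equal(tf$scale, 10)
  expect_equal(tf$translation, c(10, 8))
  expect_error(estimate_transform(pairs), "nominal_scale")
})

test_that("transform errors shrink as correspondences accumulate", {
  set.seed(12)
  sigma <- 2
  err_at_n <- function(n) {
    mean(replicate(40, {
      b <- cbind(runif(n, 1, 80), runif(n, 1, 80))
      m <- 10 * b + matrix(c(12.5, 8), n, 2, byrow = TRUE) +
        matrix(rnorm(2 * n, 0, sigma), n, 2)
      tf <- estimate_transform(data.frame(m_row = m[, 1], m_col = m[, 2],
                                          b_row = b[, 1], b_col = b[, 2]))
      abs(tf$scale - 10) + sum(abs(tf$translation - c(12.5, 8))) / 10
    }))
  }
  errs <- vapply(c(2, 4, 8, 16), err_at_n, numeric(1))
  expect_lt(errs[4], errs[1])  # N = 16 beats N = 2
})

test_that("point projection inverts exactly and scales distances", {
  tf <- projection_transform(2, c(10, 5))
  expect_equal(unname(project_points(cbind(0, 0), tf, "b2m")[1, ]), c(10, 5))
  set.seed(13)
  p <- cbind(runif(100, 0, 80), runif(100, 0, 80))
  back <- project_points(project_points(p, tf, "b2m"), tf, "m2b")
  expect_lt(max(abs(back - p)), 1e-9)
  d0 <- dist(p); d1 <- dist(project_points(p, tf, "b2m"))
  expect_equal(as.numeric(d1), as.numeric(2 * d0), tolerance = 1e-12)
})

test_that("mask projection covers the expected biosensor block", {
  # empty mask
  tf <- projection_transform(10, c(0, 0))
  empty <- project_mask_to_biosensor(label_mask(matrix(0L, 100, 100)), tf)
  expect_length(empty$pixel_sets, 0)
  # a 30 x 30 px microscope cell at scale 10 covers about 3 x 3 biosensor px
  lab <- matrix(0L, 800, 800)
  lab[301:330, 401:430] <- 1L
  cov <- project_mask_to_biosensor(label_mask(lab), tf)
  px <- cov$pixel_sets[["1"]]
  expect_gte(nrow(px), 9)
  expect_lte(nrow(px), 16)  # boundary pixels may add a ring at most
  expect_lte(diff(range(px[, 1])), 3)
  expect_lte(diff(range(px[, 2])), 3)
  # brute-force rasterization oracle: every microscope pixel lands in its set
  mpx <- which(lab == 1L, arr.ind = TRUE)
  bpx <- unique(round((mpx - 0) / 10))
  keep <- bpx[, 1] >= 1 & bpx[, 1] <= 80 & bpx[, 2] >= 1 & bpx[, 2] <= 80
  expect_setequal(paste(px[, 1], px[, 2]),
                  paste(bpx[keep, 1], bpx[keep, 2]))
})

test_that("overlapping cells share cover pixels but the mask is single-valued", {
  lab <- matrix(0L, 100, 100)
  lab[11:30, 11:30] <- 1L
  lab[28:40, 28:40] <- 2L  # overlaps cell 1 region after projection
  tf <- projection_transform(10, c(0, 0))
  cov <- project_mask_to_biosensor(label_mask(lab), tf)
  k1 <- paste(cov$pixel_sets[["1"]][, 1], cov$pixel_sets[["1"]][, 2])
  k2 <- paste(cov$pixel_sets[["2"]][, 1], cov$pixel_sets[["2"]][, 2])
  shared <- intersect(k1, k2)
  expect_gt(length(shared), 0)
  # the single-valued mask assigns shared pixels to the majority contributor
  expect_true(all(cov$mask$labels %in% c(0L, 1L, 2L)))
})

test_that("sensor cropping produces consistent coordinates", {
  img <- matrix(rnorm(100 * 120), 100, 120)
  tfi <- projection_transform(1, c(0, 0))
  cr <- crop_to_sensor(img, tfi, sensor_shape = c(100, 120))
  expect_identical(cr$image, img)
  expect_equal(cr$offset, c(0, 0))
  # scale 10, 80 x 80 sensor spans an 800 x 800 crop when the image allows
  big <- matrix(0, 900, 900)
  cr2 <- crop_to_sensor(big, projection_transform(10, c(0, 0)))
  expect_equal(dim(cr2$image), c(800, 800))
  # re-projecting with the adjusted transform matches pre-crop projection
  tf3 <- projection_transform(10, c(37, 22))
  cr3 <- crop_to_sensor(matrix(0, 900, 900), tf3)
  p <- cbind(c(10, 50), c(20, 70))
  pre <- project_points(p, tf3, "b2m")
  post <- project_points(p, cr3$transform, "b2m")
  expect_equal(pre - matrix(cr3$offset, 2, 2, byrow = TRUE), post, tolerance = 1e-12)
  expect_error(crop_to_sensor(matrix(0, 10, 10), projection_transform(10, c(5000, 0))),
               "intersect")
})

test_that("transforms round-trip through JSON", {
  tf <- projection_transform(10.25, c(12.5, -3.75))
  f <- withr::local_tempfile(fileext = ".json")
  write_transform(tf, f, extra = list(adhesion_start_index = 6))
  back <- read_transform(f)
  expect_equal(back$transform$scale, tf$scale)
  expect_equal(back$transform$translation, tf$translation)
  expect_equal(back$extra$adhesion_start_index, 6)
})
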