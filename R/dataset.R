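## Dataset assembly: stratified splits, class-balancing oversampling, and
## pixel-wise online standardization (Welford).

#' Stratified train/validation/test split
#'
#' Splits labelled samples 64 % / 16.5 % / 16.5 % by default, stratified by
#' label with a largest-remainder rounding rule per class. The stated
#' ratios leave 3 % unallocated; because the splits must partition the
#' data, that surplus goes to the test set (so 1000 single-class samples
#' split 640/165/195). Train and validation class counts stay within one
#' sample of `ratio * n` per class. Deterministic for a fixed seed.
#'
#' @param samples samples tibble with a `label` column.
#' @param ratios length-3 positive target fractions for
#'   train/validation/test; must not sum to more than 1. Any shortfall
#'   from 1 enlarges the test split.
#' @param seed RNG seed.
#' @return an object of class `dataset_split`: tibbles `train`,
#'   `validation`, `test` (each a subset of `samples` plus a `.row` index
#'   into the input), and the `ratios`/`seed` used.
#' @export
split_dataset <- function(samples, ratios = c(0.64, 0.165, 0.165), seed = 1) {
  if (length(ratios) != 3 || any(ratios <= 0) || sum(ratios) > 1 + 1e-9) {
    abort("`ratios` must be three positive fractions summing to at most 1")
  }
  if (!"label" %in% names(samples) || anyNA(samples$label)) {
    abort("every sample must carry a non-missing `label`")
  }
  counts <- table(samples$label)
  if (any(counts < 3)) {
    abort(sprintf("class '%s' has fewer than 3 samples; cannot stratify",
                  names(counts)[which.min(counts)]))
  }
  samples$.row <- seq_len(nrow(samples))
  assign_split <- function(n) {
    # largest-remainder apportionment; structural surplus (1 - sum(ratios))
    # goes to the test split
    raw <- n * ratios
    base <- floor(raw)
    rem <- n - sum(base)
    frac <- order(raw - base, decreasing = TRUE)
    take <- frac[seq_len(min(rem, sum(raw - base > 1e-12)))]
    base[take] <- base[take] + 1
    base[3] <- base[3] + (n - sum(base))
    base
  }
  with_seed(seed, {
    parts <- list(train = integer(0), validation = integer(0), test = integer(0))
    for (lb in sort(unique(samples$label))) {
      idx <- sample(samples$.row[samples$label == lb])
      k <- assign_split(length(idx))
      parts$train <- c(parts$train, idx[seq_len(k[1])])
      parts$validation <- c(parts$validation, idx[k[1] + seq_len(k[2])])
      parts$test <- c(parts$test, idx[k[1] + k[2] + seq_len(k[3])])
    }
    structure(
      list(train = samples[sort(parts$train), ],
           validation = samples[sort(parts$validation), ],
           test = samples[sort(parts$test), ],
           ratios = ratios, seed = seed),
      class = "dataset_split"
    )
  })
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d / validation %d / test %d\n",
              nrow(x$train), nrow(x$validation), nrow(x$test)))
  invisible(x)
}

#' Balance classes by oversampling
#'
#' Inflates every class to the majority-class count by randomly repeating
#' its samples (with replacement); all original samples are retained.
#'
#' @param samples samples tibble with a `label` column.
#' @param seed RNG seed.
#' @return augmented tibble with `n_classes * max_count` rows.
#' @export
oversample <- function(samples, seed = 1) {
  counts <- table(samples$label)
  if (length(counts) == 0 || any(counts == 0)) abort("every class needs at least one sample")
  target <- max(counts)
  with_seed(seed, {
    parts <- lapply(names(counts), function(lb) {
      idx <- which(samples$label == lb)
      deficit <- target - length(idx)
      extra <- if (deficit > 0) sample(idx, deficit, replace = TRUE) else integer(0)
      samples[c(idx, extra), ]
    })
    dplyr::bind_rows(parts)
  })
}

#' Pixel-wise mean and standard deviation via Welford's online algorithm
#'
#' One streaming pass over the training samples, accumulating per-(frame,
#' row, col) mean and M2; the standard deviation uses the n-1 (sample)
#' denominator. Matches a two-pass computation to ~1e-10 relative and is
#' invariant to stream order at that tolerance.
#'
#' @param samples samples tibble (list-column `video`) or a plain list of
#'   equally shaped `(t, 8, 8)` arrays; use the training split only.
#' @return an object of class `standardization_stats`: `mean`, `std`
#'   (arrays of the sample shape) and `n`.
#' @export
welford_stats <- function(samples) {
  vids <- if (is.data.frame(samples)) samples$video else samples
  if (length(vids) < 2) abort("need at least 2 samples")
  shp <- dim(vids[[1]])
  mean_a <- array(0, shp)
  m2 <- array(0, shp)
  n <- 0L
  for (v in vids) {
    if (!identical(dim(v), shp)) abort("all samples must share one (t, 8, 8) shape")
    n <- n + 1L
    delta <- v - mean_a
    mean_a <- mean_a + delta / n
    m2 <- m2 + delta * (v - mean_a)
  }
  structure(list(mean = mean_a, std = sqrt(m2 / (n - 1)), n = n),
            class = "standardization_stats")
}

#' @export
print.standardization_stats <- function(x, ...) {
  cat(sprintf("<standardization_stats> n = %d, shape (%s)\n", x$n,
              paste(dim(x$mean), collapse = ", ")))
  invisible(x)
}

#' Pixel-wise standardization
#'
#' `x_s[t, w, h] = (x[t, w, h] - mean[t, w, h]) / max(std[t, w, h], eps)`;
#' the epsilon floor keeps constant border pixels finite. Validation and
#' test data must be standardized with training-set statistics.
#'
#' @param x a `(t, 8, 8)` array, or a samples tibble whose `video` column is
#'   standardized in place.
#' @param stats a [welford_stats()] result.
#' @param eps standard-deviation floor.
#' @return object of the same type as `x`.
#' @export
standardize <- function(x, stats, eps = 1e-6) {
  stopifnot(inherits(stats, "standardization_stats"))
  denom <- pmax(stats$std, eps)
  if (is.data.frame(x)) {
    x$video <- lapply(x$video, function(v) (v - stats$mean) / denom)
    return(x)
  }
  (x - stats$mean) / denom
}

#' Truncate samples to a shorter timespan
#'
#' Keeps the first `n_frames` frames of every sample video (the 30/60/90 min
#' dataset variants share samples and differ only in this prefix length).
#'
#' @param samples samples tibble.
#' @param n_frames frames to keep.
#' @return samples tibble with truncated videos.
#' @export
truncate_samples <- function(samples, n_frames) {
  samples$video <- lapply(samples$video, function(v) {
    if (dim(v)[1] < n_frames) abort("sample shorter than requested truncation")
    v[seq_len(n_frames), , , drop = FALSE]
  })
  if ("timespan_min" %in% names(samples)) samples$timespan_min <- NA_real_
  samples
}

#' Stratified k-fold assignment
#'
#' Assigns each sample to one of `n_folds` validation folds, stratified by
#' label; per-class fold sizes differ by at most one.
#'
#' @param samples samples tibble with `label`.
#' @param n_folds number of folds (default 5).
#' @param seed RNG seed.
#' @return integer vector of fold ids in `1..n_folds`.
#' @export
make_folds <- function(samples, n_folds = 5, seed = 1) {
  counts <- table(samples$label)
  if (any(counts < n_folds)) {
    abort(sprintf("class '%s' has fewer samples than folds",
                  names(counts)[which.min(counts)]))
  }
  fold <- integer(nrow(samples))
  with_seed(seed, {
    for (lb in names(counts)) {
      idx <- sample(which(samples$label == lb))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}
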