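make_sets <- function(...) {
  sets <- list(...)
  lapply(sets, function(px) {
    m <- matrix(px, ncol = 2, byrow = TRUE)
    colnames(m) <- c("row", "col")
    m
  })
}

test_that("cell matching is exact on identical masks and empty predictions", {
  truth <- make_sets(a = c(1, 1, 1, 2), b = c(5, 5, 5, 6))
  m <- match_cells(truth, truth)
  expect_true(all(m$detected))
  expect_true(all(m$dice == 1))
  expect_equal(detection_error(m), 0)
  m0 <- match_cells(list(), truth)
  expect_true(all(!m0$detected))
  expect_equal(detection_error(m0), 1)
})

test_that("greedy matching equals exhaustive optimal assignment on small toys", {
  set.seed(18)
  for (rep in 1:8) {
    n_t <- sample(2:4, 1); n_p <- sample(2:4, 1)
    truth <- lapply(1:n_t, function(i) {
      r0 <- sample(1:20, 1); c0 <- sample(1:20, 1)
      as.matrix(expand.grid(row = r0:(r0 + 2), col = c0:(c0 + 2)))
    })
    names(truth) <- paste0("t", 1:n_t)
    pred <- lapply(1:n_p, function(i) {
      r0 <- sample(1:20, 1); c0 <- sample(1:20, 1)
      as.matrix(expand.grid(row = r0:(r0 + 2), col = c0:(c0 + 2)))
    })
    names(pred) <- paste0("p", 1:n_p)
    m <- match_cells(pred, truth, min_overlap = 0.3)
    # oracle: enumerate all one-to-one assignments, maximize total intersection
    inter <- outer(seq_len(n_t), seq_len(n_p), Vectorize(function(i, j) {
      length(intersect(paste(truth[[i]][, 1], truth[[i]][, 2]),
                       paste(pred[[j]][, 1], pred[[j]][, 2])))
    }))
    best <- 0
    perms <- function(v) if (length(v) <= 1) list(v) else
      unlist(lapply(seq_along(v), function(i) lapply(perms(v[-i]), function(p) c(v[i], p))),
             recursive = FALSE)
    k <- min(n_t, n_p)
    for (ts in utils::combn(n_t, k, simplify = FALSE)) {
      for (ps in perms(seq_len(n_p))) {
        tot <- sum(inter[cbind(ts, ps[seq_len(k)])])
        best <- max(best, tot)
      }
    }
    expect_equal(sum(m$intersection), best)
  }
})

test_that("Dice dissimilarity follows the arithmetic definition", {
  truth <- make_sets(a = c(1, 1, 1, 2, 2, 1, 2, 2))
  identical_m <- match_cells(truth, truth)
  expect_equal(dice_scores(identical_m)$ds, 0)
  # |A| = |B| = 4 with |A n B| = 2: Dice 0.5, DS 0.5
  pred <- make_sets(a = c(1, 1, 1, 2, 9, 9, 9, 8))
  m <- match_cells(pred, truth, min_overlap = 0.2)
  expect_equal(m$dice[1], 0.5)
  expect_equal(dice_scores(m)$ds, 0.5)
  # disjoint matched sets score DS 1 when forced through
  pd <- make_sets(a = c(15, 15))
  md <- match_cells(pd, truth, min_overlap = 0)
  expect_equal(sum(md$intersection), 0)
  expect_error(dice_scores(md), "matched")
})

test_that("eroding predictions never improves the Dice dissimilarity", {
  set.seed(19)
  truth <- lapply(1:4, function(i) {
    r0 <- sample(5:60, 1); c0 <- sample(5:60, 1)
    as.matrix(expand.grid(row = r0:(r0 + 3), col = c0:(c0 + 3)))
  })
  names(truth) <- paste0("t", 1:4)
  erode <- function(sets, k) lapply(sets, function(px) px[seq_len(max(1, nrow(px) - k)), , drop = FALSE])
  ds_at <- function(k) {
    ev <- evaluate_segmentation(erode(truth, k), truth, min_overlap = 0.05)
    ev$DS
  }
  ds <- vapply(c(0, 4, 8, 12), ds_at, numeric(1))
  expect_true(all(diff(ds) >= -1e-12))
})

test_that("classification metrics match hand-enumerated values", {
  # perfect one-hot predictions
  truth <- c("a", "a", "b", "b", "c")
  probs <- matrix(0, 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  probs[cbind(1:5, match(truth, colnames(probs)))] <- 1
  rep1 <- classification_report(probs, truth)
  expect_equal(rep1$accuracy, 1)
  expect_equal(rep1$f1, 1)
  expect_equal(rep1$auc, 1)
  expect_equal(rep1$auc_pr, 1)
  expect_equal(unname(diag(rep1$confusion)), rep(1, 3))
  expect_equal(unname(rowSums(rep1$confusion)), rep(1, 3), tolerance = 1e-9)

  # uniform probabilities on balanced two-class truth: AUC 0.5
  u <- matrix(0.5, 10, 2, dimnames = list(NULL, c("a", "b")))
  rep2 <- classification_report(u, rep(c("a", "b"), 5))
  expect_equal(rep2$auc, 0.5)
})

test_that("AUC and AUC-PR agree with a brute-force threshold sweep", {
  set.seed(20)
  for (rep in 1:5) {
    n <- 10
    score <- round(runif(n), 2)
    pos <- runif(n) > 0.5
    if (!any(pos) || all(pos)) next
    # brute-force AUC: probability a positive outranks a negative (ties 0.5)
    pairs <- expand.grid(p = which(pos), n = which(!pos))
    auc_bf <- mean(ifelse(score[pairs$p] > score[pairs$n], 1,
                          ifelse(score[pairs$p] == score[pairs$n], 0.5, 0)))
    expect_equal(adhekin:::binary_auc(score, pos), auc_bf)
    # brute-force AP: exhaustive threshold enumeration
    th <- sort(unique(score), decreasing = TRUE)
    rec_prev <- 0; ap <- 0
    for (t in th) {
      sel <- score >= t
      prec <- sum(pos & sel) / sum(sel)
      rec <- sum(pos & sel) / sum(pos)
      ap <- ap + (rec - rec_prev) * prec
      rec_prev <- rec
    }
    expect_equal(adhekin:::binary_average_precision(score, pos), ap)
  }
})

test_that("macro metrics on a 10-sample toy equal hand-computed values", {
  truth <- c("a", "a", "a", "b", "b", "b", "b", "a", "a", "b")
  pa <- c(0.9, 0.8, 0.4, 0.3, 0.2, 0.6, 0.1, 0.7, 0.55, 0.45)
  probs <- cbind(a = pa, b = 1 - pa)
  rp <- classification_report(probs, truth)
  pred <- ifelse(pa >= 0.5, "a", "b")
  expect_equal(rp$accuracy, mean(pred == truth))
  f1_cls <- sapply(c("a", "b"), function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    2 * tp / (2 * tp + fp + fn)
  })
  expect_equal(rp$f1, mean(f1_cls))
  expect_equal(rp$auc, mean(c(adhekin:::binary_auc(pa, truth == "a"),
                              adhekin:::binary_auc(1 - pa, truth == "b"))))
})

test_that("absent classes are skipped in macro averages with a warning", {
  probs <- matrix(c(0.7, 0.2, 0.1, 0.6, 0.3, 0.1), 2, 3, byrow = TRUE,
                  dimnames = list(NULL, c("a", "b", "c")))
  expect_warning(rp <- classification_report(probs, c("a", "b")), "absent")
  expect_true(is.finite(rp$f1))
})

test_that("t-SNE embeddings are deterministic and preserve separation", {
  set.seed(21)
  p1 <- cbind(a = runif(40, 0.85, 0.99), b = 0)
  p1[, "b"] <- 1 - p1[, "a"]
  p2 <- cbind(a = runif(40, 0.01, 0.15), b = 0)
  p2[, "b"] <- 1 - p2[, "a"]
  probs <- rbind(p1, p2)
  emb <- embed_probabilities(probs, perplexity = 10, n_iter = 300, seed = 5)
  expect_equal(nrow(emb), 80)
  emb2 <- embed_probabilities(probs, perplexity = 10, n_iter = 300, seed = 5)
  expect_identical(emb, emb2)
  # nearest-centroid purity of the two clusters
  lab <- rep(c(1, 2), each = 40)
  cent <- rbind(colMeans(emb[lab == 1, ]), colMeans(emb[lab == 2, ]))
  d <- adhekin:::cross_dist(as.matrix(emb), as.matrix(cent))
  purity <- mean(apply(d, 1, which.min) == lab)
  expect_gte(purity, 0.95)
  expect_error(embed_probabilities(probs[1:10, ], perplexity = 10), "rows")
})
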