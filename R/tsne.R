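## Exact t-distributed stochastic neighbor embedding for probability
## vectors. n here is at most a few thousand (one row per classified cell),
## so the O(n^2) exact gradient is appropriate; no tree approximation.

tsne_p_matrix <- function(x, perplexity) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { h <- 0 } else {
        p <- w / sw
        h <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / max(sum(w), .Machine$double.eps)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' 2D t-SNE embedding of probability vectors
#'
#' Visualizes how a classifier separates cell types by embedding its output
#' probability vectors in the plane. Exact (dense) t-SNE with perplexity
#' calibration by binary search, early exaggeration and momentum gradient
#' descent; deterministic for a fixed seed.
#'
#' @param probabilities matrix/data frame of per-class scores (a
#'   `.pred_class` column is ignored).
#' @param perplexity effective neighbor count (must satisfy
#'   `nrow >= 3 * perplexity + 2`; lower it for small sets).
#' @param n_iter gradient-descent iterations.
#' @param seed RNG seed for the initial layout.
#' @return a tibble with columns `tsne_1`, `tsne_2`, one row per input row.
#' @export
embed_probabilities <- function(probabilities, perplexity = 30, n_iter = 500,
                                seed = 1) {
  x <- as.data.frame(probabilities)
  x$.pred_class <- NULL
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3 * perplexity + 2) {
    abort(sprintf("need at least %d rows for perplexity %g (have %d)",
                  ceiling(3 * perplexity + 2), perplexity, n))
  }
  P <- tsne_p_matrix(x, perplexity)
  with_seed(seed, {
    y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    inc <- matrix(0, n, 2)
    momentum <- 0.5
    lr <- 200
    exag <- 12
    for (iter in seq_len(n_iter)) {
      Pe <- if (iter <= 100) P * exag else P
      d2 <- as.matrix(stats::dist(y))^2
      num <- 1 / (1 + d2)
      diag(num) <- 0
      Q <- num / sum(num)
      Q <- pmax(Q, 1e-12)
      W <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(W)) %*% y - W %*% y)
      if (iter == 250) momentum <- 0.8
      inc <- momentum * inc - lr * grad
      y <- y + inc
      y <- sweep(y, 2, colMeans(y))
    }
    tibble(tsne_1 = y[, 1], tsne_2 = y[, 2])
  })
}
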