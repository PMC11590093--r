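## Minimal neural-network engine: matrix-multiply (im2col) 3D convolution,
## pooling, layer normalization, dropout, linear and LSTM layers with manual
## backpropagation. Activations are arrays laid out (C, T, H, W, B) --
## channel fastest, batch last -- so im2col reduces to one index gather and
## one matrix product. Each layer is an environment exposing
## forward(x, train), backward(dy), params and grads.

nn_uniform_init <- function(nrow, ncol, fan_in) {
  k <- 1 / sqrt(fan_in)
  matrix(runif(nrow * ncol, -k, k), nrow, ncol)
}

#' @noRd
layer_conv3d <- function(in_ch, out_ch, in_dim) {
  # in_dim = c(T, H, W); kernel 3x3x3, pad 1, stride 1 (shape preserving).
  # The convolution is computed as a sum over the 27 kernel offsets of a
  # channel matmul against the correspondingly shifted slab of the padded
  # input -- equivalent to im2col but without materializing the (27 *
  # in_ch) x (T*H*W*B) patch matrix, which dominates time and memory for
  # wide inputs.
  Tt <- in_dim[1]; H <- in_dim[2]; W <- in_dim[3]
  Tp <- Tt + 2L; Hp <- H + 2L; Wp <- W + 2L
  n_out_pos <- Tt * H * W
  offsets <- expand.grid(dt = 0:2, dh = 0:2, dw = 0:2)  # dt fastest, like W's blocks

  env <- new.env(parent = emptyenv())
  env$type <- "conv3d"
  env$out_dim <- c(Tt, H, W)
  # W columns ordered (channel fastest, then dt, dh, dw)
  env$params <- list(W = nn_uniform_init(out_ch, in_ch * 27, in_ch * 27),
                     b = matrix(runif(out_ch, -1, 1) / sqrt(in_ch * 27), out_ch, 1))
  env$grads <- list(W = NULL, b = NULL)
  it <- 1L + seq_len(Tt); ih <- 1L + seq_len(H); iw <- 1L + seq_len(W)

  slab <- function(xp, k, B) {
    s <- xp[, offsets$dt[k] + seq_len(Tt), offsets$dh[k] + seq_len(H),
            offsets$dw[k] + seq_len(W), , drop = FALSE]
    dim(s) <- c(in_ch, n_out_pos * B)
    s
  }
  env$forward <- function(x, train = TRUE) {
    B <- dim(x)[5]
    xp <- array(0, c(in_ch, Tp, Hp, Wp, B))
    xp[, it, ih, iw, ] <- x
    Y <- matrix(as.vector(env$params$b), out_ch, n_out_pos * B)
    for (k in 1:27) {
      Wk <- env$params$W[, (k - 1L) * in_ch + seq_len(in_ch), drop = FALSE]
      Y <- Y + Wk %*% slab(xp, k, B)
    }
    env$cache <- list(xp = xp, B = B)
    array(Y, c(out_ch, Tt, H, W, B))
  }
  env$backward <- function(dy) {
    # input gradient as a transposed convolution: slab matmuls over the
    # padded dy with reversed offsets; avoids scatter-accumulation
    B <- env$cache$B
    xp <- env$cache$xp
    env$cache <- NULL
    dy_mat <- matrix(dy, out_ch, n_out_pos * B)
    dyp <- array(0, c(out_ch, Tp, Hp, Wp, B))
    dyp[, it, ih, iw, ] <- dy
    dy_slab <- function(k) {
      s <- dyp[, (2L - offsets$dt[k]) + seq_len(Tt),
               (2L - offsets$dh[k]) + seq_len(H),
               (2L - offsets$dw[k]) + seq_len(W), , drop = FALSE]
      dim(s) <- c(out_ch, n_out_pos * B)
      s
    }
    gW <- matrix(0, out_ch, in_ch * 27L)
    dx_mat <- matrix(0, in_ch, n_out_pos * B)
    for (k in 1:27) {
      cols <- (k - 1L) * in_ch + seq_len(in_ch)
      gW[, cols] <- tcrossprod(dy_mat, slab(xp, k, B))
      dx_mat <- dx_mat + crossprod(env$params$W[, cols, drop = FALSE], dy_slab(k))
    }
    env$grads$W <- gW
    env$grads$b <- matrix(rowSums(dy_mat), out_ch, 1)
    array(dx_mat, c(in_ch, Tt, H, W, B))
  }
  env
}

#' @noRd
layer_relu <- function() {
  env <- new.env(parent = emptyenv())
  env$type <- "relu"
  env$params <- list(); env$grads <- list()
  env$forward <- function(x, train = TRUE) {
    env$cache <- x > 0
    x * env$cache
  }
  env$backward <- function(dy) {
    out <- dy * env$cache
    env$cache <- NULL
    out
  }
  env
}

#' @noRd
layer_dropout <- function(rate = 0.2) {
  env <- new.env(parent = emptyenv())
  env$type <- "dropout"
  env$params <- list(); env$grads <- list()
  env$forward <- function(x, train = TRUE) {
    if (!train || rate == 0) {
      env$cache <- NULL
      return(x)
    }
    mask <- array(stats::rbinom(length(x), 1, 1 - rate) / (1 - rate), dim(x))
    env$cache <- mask
    x * mask
  }
  env$backward <- function(dy) {
    if (is.null(env$cache)) return(dy)
    out <- dy * env$cache
    env$cache <- NULL
    out
  }
  env
}

#' @noRd
layer_layernorm <- function(n_channels, n_features, eps = 1e-5) {
  # normalizes each sample over all (C, T, H, W) features; affine per channel
  env <- new.env(parent = emptyenv())
  env$type <- "layernorm"
  env$params <- list(gamma = matrix(1, n_channels, 1),
                     beta = matrix(0, n_channels, 1))
  env$grads <- list(gamma = NULL, beta = NULL)
  group <- rep(seq_len(n_channels), times = n_features / n_channels)

  env$forward <- function(x, train = TRUE) {
    shp <- dim(x)
    B <- shp[length(shp)]
    xm <- matrix(x, n_features, B)
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    v <- colMeans(xc^2)
    inv <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2, inv, "*")
    g_full <- env$params$gamma[group, 1]
    b_full <- env$params$beta[group, 1]
    y <- xhat * g_full + b_full
    env$cache <- list(xhat = xhat, inv = inv, shp = shp, g_full = g_full)
    array(y, shp)
  }
  env$backward <- function(dy) {
    cc <- env$cache
    B <- cc$shp[length(cc$shp)]
    dym <- matrix(dy, n_features, B)
    env$grads$gamma <- matrix(rowsum(rowSums(dym * cc$xhat), group), ncol = 1)
    env$grads$beta <- matrix(rowsum(rowSums(dym), group), ncol = 1)
    dxhat <- dym * cc$g_full
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * cc$xhat)
    dx <- sweep(dxhat, 2, m1) - sweep(cc$xhat, 2, m2, "*")
    dx <- sweep(dx, 2, cc$inv, "*")
    env$cache <- NULL
    array(dx, cc$shp)
  }
  env
}

#' @noRd
layer_maxpool3d <- function(pool, in_dim) {
  # pool = c(pt, ph, pw), stride = pool, tail cropped
  Tt <- in_dim[1]; H <- in_dim[2]; W <- in_dim[3]
  T2 <- Tt %/% pool[1]; H2 <- H %/% pool[2]; W2 <- W %/% pool[3]
  offsets <- expand.grid(dt = seq_len(pool[1]), dh = seq_len(pool[2]),
                         dw = seq_len(pool[3]))
  env <- new.env(parent = emptyenv())
  env$type <- "maxpool3d"
  env$out_dim <- c(T2, H2, W2)
  env$params <- list(); env$grads <- list()
  env$forward <- function(x, train = TRUE) {
    C <- dim(x)[1]; B <- dim(x)[5]
    y <- NULL; amax <- NULL
    for (k in seq_len(nrow(offsets))) {
      xs <- x[, seq(offsets$dt[k], by = pool[1], length.out = T2),
              seq(offsets$dh[k], by = pool[2], length.out = H2),
              seq(offsets$dw[k], by = pool[3], length.out = W2), , drop = FALSE]
      if (is.null(y)) {
        y <- xs
        amax <- array(1L, dim(xs))
      } else {
        better <- xs > y
        y[better] <- xs[better]
        amax[better] <- k
      }
    }
    env$cache <- list(amax = amax, in_shape = dim(x))
    y
  }
  env$backward <- function(dy) {
    cc <- env$cache
    dx <- array(0, cc$in_shape)
    for (k in seq_len(nrow(offsets))) {
      contrib <- dy * (cc$amax == k)
      dx[, seq(offsets$dt[k], by = pool[1], length.out = T2),
         seq(offsets$dh[k], by = pool[2], length.out = H2),
         seq(offsets$dw[k], by = pool[3], length.out = W2), ] <-
        dx[, seq(offsets$dt[k], by = pool[1], length.out = T2),
           seq(offsets$dh[k], by = pool[2], length.out = H2),
           seq(offsets$dw[k], by = pool[3], length.out = W2), , drop = FALSE] + contrib
    }
    env$cache <- NULL
    dx
  }
  env
}

#' @noRd
layer_adaptive_avgpool_t <- function(in_t, target_t) {
  # average pooling of the temporal axis into target_t near-equal bins
  starts <- floor((seq_len(target_t) - 1) * in_t / target_t) + 1L
  ends <- ceiling(seq_len(target_t) * in_t / target_t)
  env <- new.env(parent = emptyenv())
  env$type <- "adaptive_avgpool_t"
  env$params <- list(); env$grads <- list()
  env$forward <- function(x, train = TRUE) {
    d <- dim(x)
    y <- array(0, c(d[1], target_t, d[3], d[4], d[5]))
    for (i in seq_len(target_t)) {
      seg <- x[, starts[i]:ends[i], , , , drop = FALSE]
      y[, i, , , ] <- apply_mean_t(seg)
    }
    env$cache <- d
    y
  }
  env$backward <- function(dy) {
    d <- env$cache
    dx <- array(0, d)
    for (i in seq_len(target_t)) {
      len <- ends[i] - starts[i] + 1L
      share <- dy[, i, , , , drop = FALSE] / len
      for (t in starts[i]:ends[i]) {
        dx[, t, , , ] <- dx[, t, , , ] + array(share, dim(share)[-2])
      }
    }
    env$cache <- NULL
    dx
  }
  env
}

# mean over the temporal axis of a (C, T, H, W, B) slab, returning (C, H, W, B)
apply_mean_t <- function(seg) {
  d <- dim(seg)
  out <- array(0, d[-2])
  for (t in seq_len(d[2])) out <- out + array(seg[, t, , , , drop = FALSE], d[-2])
  out / d[2]
}

#' @noRd
layer_flatten <- function() {
  env <- new.env(parent = emptyenv())
  env$type <- "flatten"
  env$params <- list(); env$grads <- list()
  env$forward <- function(x, train = TRUE) {
    d <- dim(x)
    env$cache <- d
    matrix(x, prod(d[-length(d)]), d[length(d)])
  }
  env$backward <- function(dy) {
    d <- env$cache
    env$cache <- NULL
    array(dy, d)
  }
  env
}

#' @noRd
layer_linear <- function(in_features, out_features) {
  env <- new.env(parent = emptyenv())
  env$type <- "linear"
  env$params <- list(W = nn_uniform_init(out_features, in_features, in_features),
                     b = matrix(runif(out_features, -1, 1) / sqrt(in_features),
                                out_features, 1))
  env$grads <- list(W = NULL, b = NULL)
  env$forward <- function(x, train = TRUE) {
    env$cache <- x
    env$params$W %*% x + as.vector(env$params$b)
  }
  env$backward <- function(dy) {
    env$grads$W <- tcrossprod(dy, env$cache)
    env$grads$b <- matrix(rowSums(dy), ncol = 1)
    out <- crossprod(env$params$W, dy)
    env$cache <- NULL
    out
  }
  env
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' @noRd
layer_lstm <- function(input_size, hidden_size, n_layers = 3) {
  # stacked LSTM; input (D, T, B); returns the last layer's final hidden
  # state (H, B). Gate order i, f, g, o in the stacked weight matrices.
  env <- new.env(parent = emptyenv())
  env$type <- "lstm"
  env$params <- list()
  env$grads <- list()
  for (l in seq_len(n_layers)) {
    d_in <- if (l == 1) input_size else hidden_size
    env$params[[paste0("W", l)]] <- nn_uniform_init(4 * hidden_size, d_in, hidden_size)
    env$params[[paste0("U", l)]] <- nn_uniform_init(4 * hidden_size, hidden_size, hidden_size)
    bias <- matrix(0, 4 * hidden_size, 1)
    bias[hidden_size + seq_len(hidden_size), 1] <- 1  # forget-gate bias
    env$params[[paste0("b", l)]] <- bias
  }
  gi <- seq_len(hidden_size)
  gf <- hidden_size + gi
  gg <- 2 * hidden_size + gi
  go <- 3 * hidden_size + gi

  env$forward <- function(x, train = TRUE) {
    Tt <- dim(x)[2]; B <- dim(x)[3]
    cache <- vector("list", n_layers)
    inp <- x
    for (l in seq_len(n_layers)) {
      Wl <- env$params[[paste0("W", l)]]
      Ul <- env$params[[paste0("U", l)]]
      bl <- as.vector(env$params[[paste0("b", l)]])
      h <- matrix(0, hidden_size, B)
      cst <- matrix(0, hidden_size, B)
      steps <- vector("list", Tt)
      hs <- array(0, c(hidden_size, Tt, B))
      for (t in seq_len(Tt)) {
        xt <- matrix(inp[, t, ], nrow = dim(inp)[1], ncol = B)
        z <- Wl %*% xt + Ul %*% h + bl
        i_g <- sigmoid(z[gi, , drop = FALSE])
        f_g <- sigmoid(z[gf, , drop = FALSE])
        g_g <- tanh(z[gg, , drop = FALSE])
        o_g <- sigmoid(z[go, , drop = FALSE])
        c_new <- f_g * cst + i_g * g_g
        tc <- tanh(c_new)
        h_new <- o_g * tc
        steps[[t]] <- list(xt = xt, h_prev = h, c_prev = cst,
                           i = i_g, f = f_g, g = g_g, o = o_g, tc = tc)
        h <- h_new; cst <- c_new
        hs[, t, ] <- h
      }
      cache[[l]] <- list(steps = steps, input = inp)
      inp <- hs
    }
    env$cache <- list(layers = cache, Tt = Tt, B = B)
    matrix(inp[, Tt, ], hidden_size, B)
  }

  env$backward <- function(dy) {
    cc <- env$cache
    Tt <- cc$Tt; B <- cc$B
    d_next <- NULL  # gradient wrt the current layer's output sequence
    for (l in rev(seq_len(n_layers))) {
      lc <- cc$layers[[l]]
      d_in_feat <- nrow(lc$steps[[1]]$xt)
      Wl <- env$params[[paste0("W", l)]]
      Ul <- env$params[[paste0("U", l)]]
      gW <- matrix(0, 4 * hidden_size, d_in_feat)
      gU <- matrix(0, 4 * hidden_size, hidden_size)
      gb <- matrix(0, 4 * hidden_size, 1)
      dh <- matrix(0, hidden_size, B)
      dc <- matrix(0, hidden_size, B)
      dx_seq <- array(0, c(d_in_feat, Tt, B))
      for (t in rev(seq_len(Tt))) {
        s <- lc$steps[[t]]
        dh_t <- dh
        if (l == n_layers) {
          if (t == Tt) dh_t <- dh_t + dy
        } else {
          dh_t <- dh_t + matrix(d_next[, t, ], hidden_size, B)
        }
        do_g <- dh_t * s$tc
        dct <- dh_t * s$o * (1 - s$tc^2) + dc
        di <- dct * s$g
        df <- dct * s$c_prev
        dg <- dct * s$i
        dc <- dct * s$f
        dz <- rbind(di * s$i * (1 - s$i),
                    df * s$f * (1 - s$f),
                    dg * (1 - s$g^2),
                    do_g * s$o * (1 - s$o))
        gW <- gW + tcrossprod(dz, s$xt)
        gU <- gU + tcrossprod(dz, s$h_prev)
        gb <- gb + matrix(rowSums(dz), ncol = 1)
        dh <- crossprod(Ul, dz)
        dx_seq[, t, ] <- crossprod(Wl, dz)
      }
      env$grads[[paste0("W", l)]] <- gW
      env$grads[[paste0("U", l)]] <- gU
      env$grads[[paste0("b", l)]] <- gb
      d_next <- dx_seq
    }
    env$cache <- NULL
    d_next  # gradient wrt the (D, T, B) input sequence
  }
  env
}

#' @noRd
softmax_probs <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# cross-entropy loss and gradient wrt logits; y is 1-based class index
softmax_ce <- function(logits, y) {
  p <- softmax_probs(logits)
  B <- ncol(p)
  picked <- p[cbind(y, seq_len(B))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlogits <- p
  dlogits[cbind(y, seq_len(B))] <- dlogits[cbind(y, seq_len(B))] - 1
  list(loss = loss, grad = dlogits / B, probs = p)
}
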