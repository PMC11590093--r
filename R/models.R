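## The four spatio-temporal classifier architectures and their training
## loop. All models map a batch of (t, 8, 8) standardized samples to a
## per-class probability vector via a softmax head.

#' Classifier model configuration
#'
#' Architectures follow a shared plan: 3 x 3 x 3 convolutions, ReLU,
#' dropout and layer normalization per block, max pooling halving the
#' spatial path 8 -> 4 -> 2 (the first pool also halves time, except in the
#' CNN-LSTM whose pooling is spatial-only), an adaptive temporal average
#' pool to a fixed length, and a two-layer fully connected head ending in a
#' softmax.
#'
#' @param architecture one of `"cnn"`, `"resnet"`, `"densenet"`, `"cnnlstm"`.
#' @param n_classes number of cell types (>= 2).
#' @param input_frames sample frame count t (>= 4).
#' @param dropout dropout rate used in every block and the head.
#' @param channels two-stage channel plan for the CNN (default `c(8, 16)`).
#' @param growth DenseNet growth rate (default 8, 4 layers per dense block).
#' @param lstm_hidden,lstm_layers LSTM size (defaults 256, 3).
#' @param head_hidden width of the first fully connected head layer.
#' @param target_t temporal length after the adaptive pool.
#' @param seed RNG seed for weight initialization.
#' @return an object of class `model_config`.
#' @export
model_config <- function(architecture = c("cnn", "resnet", "densenet", "cnnlstm"),
                         n_classes, input_frames, dropout = 0.2,
                         channels = c(8, 16), growth = 8,
                         lstm_hidden = 256, lstm_layers = 3,
                         head_hidden = 64, target_t = 4, seed = 1) {
  architecture <- match.arg(architecture)
  if (n_classes < 2) abort("`n_classes` must be at least 2")
  if (input_frames < 4) abort("`input_frames` must be at least 4")
  structure(
    list(architecture = architecture, n_classes = as.integer(n_classes),
         input_frames = as.integer(input_frames), dropout = dropout,
         channels = channels, growth = growth, lstm_hidden = lstm_hidden,
         lstm_layers = lstm_layers, head_hidden = head_hidden,
         target_t = target_t, seed = seed),
    class = "model_config"
  )
}

#' Training configuration
#'
#' Defaults mirror the study regime: Adam with learning rate 1e-4 and
#' weight decay 1e-5, cross-entropy loss, at most 250 epochs with early
#' stopping on validation loss, 5-fold stratified cross-validation.
#'
#' @param max_epochs,lr,weight_decay,batch_size,patience,n_folds,seed
#'   training hyperparameters.
#' @return an object of class `train_config`.
#' @export
train_config <- function(max_epochs = 250, lr = 1e-4, weight_decay = 1e-5,
                         batch_size = 32, patience = 25, n_folds = 5, seed = 1) {
  if (max_epochs < 1 || batch_size < 1 || n_folds < 2) {
    abort("`max_epochs`, `batch_size` must be positive; `n_folds` >= 2")
  }
  if (lr < 0 || weight_decay < 0) abort("`lr` and `weight_decay` must be non-negative")
  structure(list(max_epochs = as.integer(max_epochs), lr = lr,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 patience = as.integer(patience), n_folds = as.integer(n_folds),
                 seed = seed),
            class = "train_config")
}

conv_block <- function(in_ch, out_ch, dim, dropout) {
  list(conv = layer_conv3d(in_ch, out_ch, dim),
       relu = layer_relu(),
       drop = layer_dropout(dropout),
       ln = layer_layernorm(out_ch, out_ch * prod(dim)))
}

block_forward <- function(blk, x, train) {
  x <- blk$conv$forward(x, train)
  x <- blk$relu$forward(x, train)
  x <- blk$drop$forward(x, train)
  blk$ln$forward(x, train)
}

block_backward <- function(blk, dy) {
  dy <- blk$ln$backward(dy)
  dy <- blk$drop$backward(dy)
  dy <- blk$relu$backward(dy)
  blk$conv$backward(dy)
}

# 1x1x1 convolution (pointwise channel mix), used for residual projections
# and DenseNet transitions
layer_conv1x1 <- function(in_ch, out_ch) {
  env <- new.env(parent = emptyenv())
  env$type <- "conv1x1"
  env$params <- list(W = nn_uniform_init(out_ch, in_ch, in_ch),
                     b = matrix(0, out_ch, 1))
  env$grads <- list(W = NULL, b = NULL)
  env$forward <- function(x, train = TRUE) {
    d <- dim(x)
    xm <- matrix(x, d[1], prod(d[-1]))
    env$cache <- list(xm = xm, d = d)
    y <- env$params$W %*% xm + as.vector(env$params$b)
    array(y, c(out_ch, d[-1]))
  }
  env$backward <- function(dy) {
    cc <- env$cache
    dym <- matrix(dy, out_ch, prod(cc$d[-1]))
    env$grads$W <- tcrossprod(dym, cc$xm)
    env$grads$b <- matrix(rowSums(dym), ncol = 1)
    dx <- crossprod(env$params$W, dym)
    env$cache <- NULL
    array(dx, cc$d)
  }
  env
}

collect_layers <- function(x) {
  if (is.environment(x)) return(list(x))
  if (is.list(x)) return(unlist(lapply(x, collect_layers), recursive = FALSE))
  list()
}

#' Build a classifier model
#'
#' Instantiates one of the four architectures for `(t, 8, 8)` inputs. The
#' returned model is an environment with `forward(x, train)` /
#' `backward(dlogits)` over batches laid out `(1, t, 8, 8, batch)` and a
#' flat `modules` list for the optimizer.
#'
#' @param config a [model_config()].
#' @return an object of class `nn_model`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  with_seed(config$seed, build_model_impl(config))
}

build_model_impl <- function(cfg) {
  t0 <- cfg$input_frames
  dr <- cfg$dropout
  model <- new.env(parent = emptyenv())
  model$config <- cfg

  head_layers <- function(in_features) {
    list(fc1 = layer_linear(in_features, cfg$head_hidden),
         relu = layer_relu(),
         drop = layer_dropout(dr),
         fc2 = layer_linear(cfg$head_hidden, cfg$n_classes))
  }
  head_forward <- function(hd, x, train) {
    x <- hd$fc1$forward(x, train)
    x <- hd$relu$forward(x, train)
    x <- hd$drop$forward(x, train)
    hd$fc2$forward(x, train)
  }
  head_backward <- function(hd, dy) {
    dy <- hd$fc2$backward(dy)
    dy <- hd$drop$backward(dy)
    dy <- hd$relu$backward(dy)
    hd$fc1$backward(dy)
  }

  if (cfg$architecture == "cnn") {
    ch <- cfg$channels
    t1 <- t0 %/% 2
    if (t1 < 1) abort("too few frames for the temporal pooling plan")
    b1 <- conv_block(1, ch[1], c(t0, 8, 8), dr)
    p1 <- layer_maxpool3d(c(2, 2, 2), c(t0, 8, 8))
    b2 <- conv_block(ch[1], ch[2], c(t1, 4, 4), dr)
    p2 <- layer_maxpool3d(c(1, 2, 2), c(t1, 4, 4))
    atp <- layer_adaptive_avgpool_t(t1, cfg$target_t)
    fl <- layer_flatten()
    hd <- head_layers(ch[2] * cfg$target_t * 4)
    model$modules <- collect_layers(list(b1, p1, b2, p2, atp, fl, hd))
    model$forward <- function(x, train = TRUE) {
      x <- block_forward(b1, x, train); x <- p1$forward(x, train)
      x <- block_forward(b2, x, train); x <- p2$forward(x, train)
      x <- atp$forward(x, train); x <- fl$forward(x, train)
      head_forward(hd, x, train)
    }
    model$backward <- function(dy) {
      dy <- head_backward(hd, dy)
      dy <- fl$backward(dy); dy <- atp$backward(dy)
      dy <- p2$backward(dy); dy <- block_backward(b2, dy)
      dy <- p1$backward(dy); block_backward(b1, dy)
    }
  } else if (cfg$architecture == "resnet") {
    # two stages of two basic blocks, channel plans (8, 16) and (16, 32)
    res_block <- function(in_ch, out_ch, dim) {
      blk <- list(conv1 = layer_conv3d(in_ch, out_ch, dim),
                  relu1 = layer_relu(),
                  drop = layer_dropout(dr),
                  ln1 = layer_layernorm(out_ch, out_ch * prod(dim)),
                  conv2 = layer_conv3d(out_ch, out_ch, dim),
                  ln2 = layer_layernorm(out_ch, out_ch * prod(dim)),
                  relu_out = layer_relu(),
                  proj = if (in_ch != out_ch) layer_conv1x1(in_ch, out_ch) else NULL)
      blk
    }
    res_forward <- function(blk, x, train) {
      skip <- if (is.null(blk$proj)) x else blk$proj$forward(x, train)
      y <- blk$conv1$forward(x, train)
      y <- blk$relu1$forward(y, train)
      y <- blk$drop$forward(y, train)
      y <- blk$ln1$forward(y, train)
      y <- blk$conv2$forward(y, train)
      y <- blk$ln2$forward(y, train)
      blk$relu_out$forward(y + skip, train)
    }
    res_backward <- function(blk, dy) {
      dy <- blk$relu_out$backward(dy)
      dskip <- dy
      dmain <- blk$ln2$backward(dy)
      dmain <- blk$conv2$backward(dmain)
      dmain <- blk$ln1$backward(dmain)
      dmain <- blk$drop$backward(dmain)
      dmain <- blk$relu1$backward(dmain)
      dmain <- blk$conv1$backward(dmain)
      if (!is.null(blk$proj)) dskip <- blk$proj$backward(dskip)
      dmain + dskip
    }
    t1 <- t0 %/% 2
    if (t1 < 1) abort("too few frames for the temporal pooling plan")
    s1b1 <- res_block(1, 8, c(t0, 8, 8))
    s1b2 <- res_block(8, 16, c(t0, 8, 8))
    p1 <- layer_maxpool3d(c(2, 2, 2), c(t0, 8, 8))
    s2b1 <- res_block(16, 16, c(t1, 4, 4))
    s2b2 <- res_block(16, 32, c(t1, 4, 4))
    p2 <- layer_maxpool3d(c(1, 2, 2), c(t1, 4, 4))
    atp <- layer_adaptive_avgpool_t(t1, cfg$target_t)
    fl <- layer_flatten()
    hd <- head_layers(32 * cfg$target_t * 4)
    model$modules <- collect_layers(list(s1b1, s1b2, p1, s2b1, s2b2, p2, atp, fl, hd))
    model$forward <- function(x, train = TRUE) {
      x <- res_forward(s1b1, x, train); x <- res_forward(s1b2, x, train)
      x <- p1$forward(x, train)
      x <- res_forward(s2b1, x, train); x <- res_forward(s2b2, x, train)
      x <- p2$forward(x, train)
      x <- atp$forward(x, train); x <- fl$forward(x, train)
      head_forward(hd, x, train)
    }
    model$backward <- function(dy) {
      dy <- head_backward(hd, dy)
      dy <- fl$backward(dy); dy <- atp$backward(dy)
      dy <- p2$backward(dy)
      dy <- res_backward(s2b2, dy); dy <- res_backward(s2b1, dy)
      dy <- p1$backward(dy)
      dy <- res_backward(s1b2, dy); res_backward(s1b1, dy)
    }
  } else if (cfg$architecture == "densenet") {
    # stem, then two dense blocks (4 layers, growth g) with a transition
    # (1x1 conv halving channels + pool) between
    g <- cfg$growth
    dense_block <- function(in_ch, n_layers, dim) {
      lapply(seq_len(n_layers), function(i) {
        conv_block(in_ch + (i - 1) * g, g, dim, dr)
      })
    }
    t1 <- t0 %/% 2
    if (t1 < 1) abort("too few frames for the temporal pooling plan")
    stem <- conv_block(1, 8, c(t0, 8, 8), dr)
    db1 <- dense_block(8, 4, c(t0, 8, 8))
    c1_out <- 8 + 4 * g
    tr1 <- layer_conv1x1(c1_out, c1_out %/% 2)
    p1 <- layer_maxpool3d(c(2, 2, 2), c(t0, 8, 8))
    c2_in <- c1_out %/% 2
    db2 <- dense_block(c2_in, 4, c(t1, 4, 4))
    c2_out <- c2_in + 4 * g
    tr2 <- layer_conv1x1(c2_out, c2_out %/% 2)
    p2 <- layer_maxpool3d(c(1, 2, 2), c(t1, 4, 4))
    atp <- layer_adaptive_avgpool_t(t1, cfg$target_t)
    fl <- layer_flatten()
    hd <- head_layers((c2_out %/% 2) * cfg$target_t * 4)
    model$modules <- collect_layers(list(stem, db1, tr1, p1, db2, tr2, p2, atp, fl, hd))

    dense_forward <- function(blocks, x, train) {
      feats <- x
      for (blk in blocks) {
        newf <- block_forward(blk, feats, train)
        feats <- abind_ch(feats, newf)
      }
      feats
    }
    dense_backward <- function(blocks, dfeats, in_ch) {
      for (i in rev(seq_along(blocks))) {
        ch_before <- in_ch + (i - 1) * g
        dnew <- slice_ch(dfeats, ch_before + seq_len(g))
        dfeats <- slice_ch(dfeats, seq_len(ch_before))
        dfeats <- dfeats + block_backward(blocks[[i]], dnew)
      }
      dfeats
    }
    model$forward <- function(x, train = TRUE) {
      x <- block_forward(stem, x, train)
      x <- dense_forward(db1, x, train)
      x <- tr1$forward(x, train); x <- p1$forward(x, train)
      x <- dense_forward(db2, x, train)
      x <- tr2$forward(x, train); x <- p2$forward(x, train)
      x <- atp$forward(x, train); x <- fl$forward(x, train)
      head_forward(hd, x, train)
    }
    model$backward <- function(dy) {
      dy <- head_backward(hd, dy)
      dy <- fl$backward(dy); dy <- atp$backward(dy)
      dy <- p2$backward(dy); dy <- tr2$backward(dy)
      dy <- dense_backward(db2, dy, c2_in)
      dy <- p1$backward(dy); dy <- tr1$backward(dy)
      dy <- dense_backward(db1, dy, 8)
      block_backward(stem, dy)
    }
  } else { # cnnlstm
    b1 <- conv_block(1, 8, c(t0, 8, 8), dr)
    p1 <- layer_maxpool3d(c(1, 2, 2), c(t0, 8, 8))
    b2 <- conv_block(8, 16, c(t0, 4, 4), dr)
    p2 <- layer_maxpool3d(c(1, 2, 2), c(t0, 4, 4))
    b3 <- conv_block(16, 32, c(t0, 2, 2), dr)
    p3 <- layer_maxpool3d(c(1, 2, 2), c(t0, 2, 2))
    lstm <- layer_lstm(32, cfg$lstm_hidden, cfg$lstm_layers)
    hd <- head_layers(cfg$lstm_hidden)
    model$modules <- collect_layers(list(b1, p1, b2, p2, b3, p3, lstm, hd))
    model$forward <- function(x, train = TRUE) {
      x <- block_forward(b1, x, train); x <- p1$forward(x, train)
      x <- block_forward(b2, x, train); x <- p2$forward(x, train)
      x <- block_forward(b3, x, train); x <- p3$forward(x, train)
      d <- dim(x)  # (32, t, 1, 1, B)
      model$conv_out_dim <- d
      seq_in <- array(x, c(d[1], d[2], d[5]))
      h <- lstm$forward(seq_in, train)
      head_forward(hd, h, train)
    }
    model$backward <- function(dy) {
      dh <- head_backward(hd, dy)
      dseq <- lstm$backward(dh)
      dx <- array(dseq, model$conv_out_dim)
      dx <- p3$backward(dx); dx <- block_backward(b3, dx)
      dx <- p2$backward(dx); dx <- block_backward(b2, dx)
      dx <- p1$backward(dx); block_backward(b1, dx)
    }
  }
  class(model) <- "nn_model"
  model
}

abind_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[-1]))
  out[seq_len(da[1]), , , , ] <- a
  out[da[1] + seq_len(db[1]), , , , ] <- b
  out
}

slice_ch <- function(a, ch) {
  a[ch, , , , , drop = FALSE]
}

#' @export
print.nn_model <- function(x, ...) {
  n_par <- sum(vapply(x$modules, function(m) {
    sum(vapply(m$params, length, numeric(1)))
  }, numeric(1)))
  cat(sprintf("<nn_model %s> %d classes, t = %d, %s parameters\n",
              x$config$architecture, x$config$n_classes,
              x$config$input_frames, format(n_par, big.mark = ",")))
  invisible(x)
}

samples_to_batch <- function(videos) {
  d <- dim(videos[[1]])
  x <- array(0, c(1, d[1], d[2], d[3], length(videos)))
  for (i in seq_along(videos)) x[1, , , , i] <- videos[[i]]
  x
}

adam_state <- function(model) {
  lapply(model$modules, function(m) {
    lapply(m$params, function(p) list(m = array(0, dim(p)), v = array(0, dim(p))))
  })
}

adam_step <- function(model, state, lr, weight_decay, step) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (i in seq_along(model$modules)) {
    mod <- model$modules[[i]]
    for (nm in names(mod$params)) {
      gr <- mod$grads[[nm]]
      if (is.null(gr)) next
      gr <- gr + weight_decay * mod$params[[nm]]
      st <- state[[i]][[nm]]
      st$m <- b1 * st$m + (1 - b1) * gr
      st$v <- b2 * st$v + (1 - b2) * gr^2
      mhat <- st$m / (1 - b1^step)
      vhat <- st$v / (1 - b2^step)
      mod$params[[nm]] <- mod$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  state
}

snapshot_params <- function(model) {
  lapply(model$modules, function(m) m$params)
}

restore_params <- function(model, snap) {
  for (i in seq_along(model$modules)) model$modules[[i]]$params <- snap[[i]]
  invisible(model)
}

model_eval <- function(model, videos, y) {
  # loss/accuracy without dropout, in batches to bound memory
  n <- length(videos)
  bs <- 128L
  tot_loss <- 0; correct <- 0
  for (s in seq(1, n, by = bs)) {
    e <- min(s + bs - 1, n)
    x <- samples_to_batch(videos[s:e])
    logits <- model$forward(x, train = FALSE)
    sc <- softmax_ce(logits, y[s:e])
    tot_loss <- tot_loss + sc$loss * (e - s + 1)
    correct <- correct + sum(apply(sc$probs, 2, which.max) == y[s:e])
  }
  list(loss = tot_loss / n, accuracy = correct / n)
}

#' Train a classifier
#'
#' Minimizes cross-entropy with Adam, recording per-epoch train/validation
#' loss and accuracy; early-stops when the validation loss has not improved
#' for `patience` epochs and restores the best-validation-loss weights.
#' Deterministic given the seeds in the configs.
#'
#' @param model an [build_model()] model (modified in place and returned).
#' @param train_samples,validation_samples samples tibbles (`video` +
#'   `label`); standardize and oversample the training set first.
#' @param config a [train_config()].
#' @return an object of class `nn_fit`: the trained `model`, `history`
#'   tibble, `classes`, and the best epoch.
#' @export
train_model <- function(model, train_samples, validation_samples, config = train_config()) {
  stopifnot(inherits(model, "nn_model"), inherits(config, "train_config"))
  classes <- sort(unique(c(train_samples$label, validation_samples$label)))
  if (length(classes) != model$config$n_classes) {
    abort(sprintf("model expects %d classes, data has %d",
                  model$config$n_classes, length(classes)))
  }
  y_tr <- match(train_samples$label, classes)
  y_va <- match(validation_samples$label, classes)
  vids_tr <- train_samples$video
  vids_va <- validation_samples$video
  if (length(vids_tr) == 0 || length(vids_va) == 0) abort("empty training or validation set")

  history <- list()
  best <- list(loss = Inf, epoch = 0L, snap = snapshot_params(model))
  step <- 0L
  state <- adam_state(model)
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(length(vids_tr))
      ep_loss <- 0; ep_correct <- 0
      for (s in seq(1, length(ord), by = config$batch_size)) {
        e <- min(s + config$batch_size - 1, length(ord))
        bidx <- ord[s:e]
        x <- samples_to_batch(vids_tr[bidx])
        logits <- model$forward(x, train = TRUE)
        sc <- softmax_ce(logits, y_tr[bidx])
        if (!is.finite(sc$loss)) {
          abort(sprintf("non-finite loss at epoch %d (lr too high or bad inputs?)", epoch))
        }
        model$backward(sc$grad)
        step <- step + 1L
        state <- adam_step(model, state, config$lr, config$weight_decay, step)
        ep_loss <- ep_loss + sc$loss * length(bidx)
        ep_correct <- ep_correct + sum(apply(sc$probs, 2, which.max) == y_tr[bidx])
      }
      va <- model_eval(model, vids_va, y_va)
      history[[epoch]] <- tibble(
        epoch = epoch,
        train_loss = ep_loss / length(ord),
        train_accuracy = ep_correct / length(ord),
        val_loss = va$loss, val_accuracy = va$accuracy
      )
      if (va$loss < best$loss - 1e-9) {
        best <- list(loss = va$loss, epoch = epoch, snap = snapshot_params(model))
      } else if (epoch - best$epoch >= config$patience) {
        break
      }
    }
  })
  restore_params(model, best$snap)
  structure(list(model = model, history = dplyr::bind_rows(history),
                 classes = classes, best_epoch = best$epoch,
                 train_config = config),
            class = "nn_fit")
}

#' @export
print.nn_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<nn_fit %s> %d epochs (best %d), val accuracy %.3f\n",
              x$model$config$architecture, nrow(h), x$best_epoch,
              h$val_accuracy[x$best_epoch]))
  invisible(x)
}

#' Predict class probabilities
#'
#' @param fit an [train_model()] result (or an `nn_model` plus `classes`).
#' @param samples samples tibble with standardized `video` column.
#' @param batch_size evaluation batch size.
#' @return a tibble with one probability column per class (rows sum to 1)
#'   plus `.pred_class`.
#' @export
predict_proba <- function(fit, samples, batch_size = 128) {
  model <- if (inherits(fit, "nn_fit")) fit$model else fit
  classes <- if (inherits(fit, "nn_fit")) fit$classes else
    paste0("class", seq_len(model$config$n_classes))
  vids <- samples$video
  n <- length(vids)
  probs <- matrix(NA_real_, n, model$config$n_classes)
  for (s in seq(1, n, by = batch_size)) {
    e <- min(s + batch_size - 1, n)
    logits <- model$forward(samples_to_batch(vids[s:e]), train = FALSE)
    probs[s:e, ] <- t(softmax_probs(logits))
  }
  colnames(probs) <- classes
  out <- as_tibble(as.data.frame(probs))
  out$.pred_class <- classes[apply(probs, 1, which.max)]
  out
}

#' 5-fold stratified cross-validation
#'
#' Folds are formed on the train + validation pool of a [split_dataset()]
#' result (the test set stays held out). For each fold the model trains on
#' the remaining folds (standardized with that training subset's own
#' Welford statistics, oversampled) and is scored on the fold and on the
#' held-out test set.
#'
#' @param split a `dataset_split`.
#' @param mconfig a [model_config()].
#' @param tconfig a [train_config()].
#' @return a list of class `cv_result`: `folds` tibble (per-fold metrics)
#'   and `summary` tibble (mean and sd per metric).
#' @export
cross_validate <- function(split, mconfig, tconfig = train_config()) {
  stopifnot(inherits(split, "dataset_split"))
  pool <- dplyr::bind_rows(split$train, split$validation)
  fold_id <- make_folds(pool, n_folds = tconfig$n_folds, seed = tconfig$seed)
  rows <- list()
  for (f in seq_len(tconfig$n_folds)) {
    tr <- pool[fold_id != f, ]
    va <- pool[fold_id == f, ]
    stats <- welford_stats(tr)
    tr_s <- oversample(standardize(tr, stats), seed = tconfig$seed + f)
    va_s <- standardize(va, stats)
    te_s <- standardize(split$test, stats)
    mcfg <- mconfig
    mcfg$seed <- mconfig$seed + f
    fit <- train_model(build_model(mcfg), tr_s, va_s, tconfig)
    va_pred <- predict_proba(fit, va_s)
    te_pred <- predict_proba(fit, te_s)
    rows[[f]] <- tibble(
      fold = f,
      val_accuracy = mean(va_pred$.pred_class == va_s$label),
      test_accuracy = mean(te_pred$.pred_class == te_s$label),
      best_epoch = fit$best_epoch
    )
  }
  folds <- dplyr::bind_rows(rows)
  summary <- tidyr::pivot_longer(folds[, c("val_accuracy", "test_accuracy")],
                                 dplyr::everything(),
                                 names_to = "metric", values_to = "value")
  summary <- dplyr::summarise(dplyr::group_by(summary, .data$metric),
                              mean = mean(.data$value), sd = sd(.data$value),
                              .groups = "drop")
  structure(list(folds = folds, summary = summary), class = "cv_result")
}
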