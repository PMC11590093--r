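test_that("every architecture outputs normalized probabilities at any length", {
  for (arch in c("cnn", "resnet", "densenet", "cnnlstm")) {
    for (t in c(14, 27, 40)) {  # 30/60/90-minute-equivalent frame grids
      m <- build_model(model_config(arch, n_classes = 3, input_frames = t, seed = 1))
      x <- array(rnorm(1 * t * 8 * 8 * 5), c(1, t, 8, 8, 5))
      logits <- m$forward(x, train = FALSE)
      expect_equal(dim(logits), c(3, 5))
      p <- adhekin:::softmax_probs(logits)
      expect_equal(colSums(p), rep(1, 5), tolerance = 1e-6)
    }
  }
  expect_error(model_config("cnn", n_classes = 1, input_frames = 10), "classes")
  expect_error(model_config("cnn", n_classes = 3, input_frames = 2), "frames")
})

test_that("the feature extractor compresses the spatial grid to 2 x 2", {
  cfg <- model_config("cnn", n_classes = 2, input_frames = 12, seed = 1)
  m <- build_model(cfg)
  # the head's first linear layer consumes channels * target_t * 2 * 2
  fc1 <- Filter(function(mod) mod$type == "linear", m$modules)[[1]]
  expect_equal(ncol(fc1$params$W), 16 * cfg$target_t * 2 * 2)
})

test_that("training with zero learning rate leaves parameters untouched", {
  s <- make_toy_samples(6, T = 6, seed = 5)
  m <- build_model(model_config("cnn", 2, 6, dropout = 0, seed = 2))
  before <- lapply(m$modules, function(mod) mod$params)
  fit <- train_model(m, s, s, train_config(max_epochs = 2, lr = 0, weight_decay = 0,
                                           batch_size = 8, patience = 5, seed = 1))
  after <- lapply(fit$model$modules, function(mod) mod$params)
  expect_identical(before, after)
  expect_equal(sd(fit$history$train_loss), 0, tolerance = 1e-9)
})

test_that("the network can drive training loss near zero on a tiny set", {
  s <- make_toy_samples(5, T = 6, gap = 4, noise = 2, seed = 6)
  m <- build_model(model_config("cnn", 2, 6, dropout = 0, seed = 3))
  fit <- train_model(m, s, s, train_config(max_epochs = 60, lr = 3e-3,
                                           weight_decay = 0, batch_size = 10,
                                           patience = 60, seed = 2))
  expect_lt(min(fit$history$train_loss), 0.05)
})

test_that("separable two-class data reaches high validation accuracy quickly", {
  tr <- make_toy_samples(20, T = 8, gap = 6, noise = 1, seed = 7)
  va <- make_toy_samples(8, T = 8, gap = 6, noise = 1, seed = 8)
  st <- welford_stats(tr)
  fit <- train_model(build_model(model_config("cnn", 2, 8, seed = 4)),
                     standardize(tr, st), standardize(va, st),
                     train_config(max_epochs = 30, lr = 1e-3, batch_size = 16,
                                  patience = 30, seed = 3))
  expect_gte(max(fit$history$val_accuracy), 0.95)
})

test_that("prediction is batching-invariant and argmax-consistent", {
  tr <- make_toy_samples(10, T = 6, seed = 9)
  st <- welford_stats(tr)
  trs <- standardize(tr, st)
  fit <- train_model(build_model(model_config("cnn", 2, 6, seed = 5)), trs, trs,
                     train_config(max_epochs = 3, lr = 1e-3, batch_size = 8,
                                  patience = 5, seed = 4))
  p_all <- predict_proba(fit, trs)
  p_one <- predict_proba(fit, trs[3, ])
  expect_equal(as.numeric(p_one[1, c("a", "b")]), as.numeric(p_all[3, c("a", "b")]),
               tolerance = 1e-10)
  probs <- as.matrix(p_all[, c("a", "b")])
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)
  expect_equal(p_all$.pred_class, c("a", "b")[apply(probs, 1, which.max)])
})

test_that("non-finite losses abort with a diagnostic", {
  s <- make_toy_samples(4, T = 6, seed = 10)
  m <- build_model(model_config("cnn", 2, 6, seed = 6))
  # poison the classifier head so the loss itself turns non-finite
  head_fc <- Filter(function(mod) mod$type == "linear", m$modules)
  head_fc[[length(head_fc)]]$params$W[] <- NaN
  expect_error(
    train_model(m, s, s, train_config(max_epochs = 2, lr = 1e-3, batch_size = 8,
                                      patience = 2, seed = 5)),
    "loss")
})

test_that("cross-validation partitions the pool and summarizes folds", {
  s <- make_toy_samples(15, T = 6, gap = 6, seed = 11)
  sp <- split_dataset(s, seed = 2)
  cv <- cross_validate(sp, model_config("cnn", 2, 6, seed = 7),
                       train_config(max_epochs = 2, lr = 1e-3, batch_size = 16,
                                    patience = 2, n_folds = 5, seed = 6))
  expect_equal(nrow(cv$folds), 5)
  expect_true(all(c("val_accuracy", "test_accuracy") %in% names(cv$folds)))
  sm <- cv$summary
  expect_equal(sm$mean[sm$metric == "val_accuracy"], mean(cv$folds$val_accuracy))
  # fold assignment itself: every pool sample in exactly one validation fold
  pool <- dplyr::bind_rows(sp$train, sp$validation)
  f <- make_folds(pool, 5, seed = 6)
  expect_equal(sort(unlist(lapply(1:5, function(k) which(f == k)))), seq_len(nrow(pool)))
  tabs <- table(f, pool$label)
  expect_lte(max(apply(tabs, 2, function(x) max(x) - min(x))), 1)
})

test_that("tidy and glance expose training results", {
  s <- make_toy_samples(6, T = 6, seed = 12)
  fit <- train_model(build_model(model_config("cnn", 2, 6, seed = 8)), s, s,
                     train_config(max_epochs = 2, lr = 1e-3, batch_size = 8,
                                  patience = 2, seed = 7))
  td <- generics::tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  gl <- generics::glance(fit)
  expect_equal(gl$architecture, "cnn")
  expect_equal(gl$epochs, 2)
})
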