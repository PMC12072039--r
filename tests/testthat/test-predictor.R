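test_that("fuse concatenates PPI block first and slicing recovers both", {
  expect_equal(fuse(c(1, 2), 3), c(1, 2, 3))
  set.seed(1)
  P <- matrix(rnorm(10), 5, 2)
  Q <- matrix(rnorm(5), 5, 1)
  F <- fuse(P, Q)
  expect_equal(F[, 1:2], P)
  expect_equal(F[, 3, drop = FALSE], Q)
  expect_equal(fuse(P, matrix(0, 5, 1))[, 3], rep(0, 5))
  expect_error(fuse(P, Q[1:3, , drop = FALSE]), "row count")
})

test_that("classify is a sigmoid affine map matching a per-term loop", {
  M <- 4; k <- 3
  # zero weights: all scores 0.5
  expect_equal(classify(rnorm(k), matrix(0, M, k), rep(0, M)), rep(0.5, M))
  # saturation
  expect_equal(classify(rnorm(k), matrix(0, M, k), rep(30, M)), rep(1, M),
               tolerance = 1e-12)
  set.seed(2)
  W <- matrix(rnorm(M * k), M, k)
  b <- rnorm(M)
  emb <- rnorm(k)
  ref <- numeric(M)
  for (j in 1:M) ref[j] <- 1 / (1 + exp(-(sum(W[j, ] * emb) + b[j])))
  expect_equal(classify(emb, W, b), ref, tolerance = 1e-12)
  # batch form
  E <- matrix(rnorm(2 * k), 2, k)
  S <- classify(E, W, b)
  expect_equal(S[1, ], classify(E[1, ], W, b))
})

test_that("bce_loss matches its closed forms", {
  Y <- matrix(c(1, 0, 1, 1), 2, 2)
  expect_equal(bce_loss(Y, matrix(0.5, 2, 2)), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(Y, pmin(pmax(Y, 1e-7), 1 - 1e-7)), 2e-7)
  # hand evaluation on a 1x2 batch
  expect_equal(bce_loss(matrix(c(1, 0), 1, 2), matrix(c(0.8, 0.4), 1, 2)),
               -(log(0.8) + log(0.6)) / 2, tolerance = 1e-12)
  expect_error(bce_loss(Y, matrix(NaN, 2, 2)), "NaN")
  expect_error(bce_loss(Y, matrix(0.5, 3, 2)), "shape")
})

test_that("backward gradients agree with finite differences", {
  bundle <- tiny_bundle(sim_config(n_modules = 2, proteins_per_module = 4,
                                   emb_dim = 6, m_features = 10,
                                   features_per_module = 4, n_terms = 4,
                                   terms_per_module = 2, seed = 3))
  data <- bundle$data
  tc <- training_config(hidden_d = 5, dropout = 0, seed = 9)
  model <- init_model(ncol(data$X), ncol(data$Hseq), data$terms, tc)
  p <- model$params
  cfg <- model$config
  n <- length(data$ids)
  M <- length(data$terms)
  loss_at <- function(p) {
    fc <- gtgo:::model_forward_cache(p, cfg, data$X, data$A_hat, data$Hseq)
    bce_loss(data$Y, fc$S)
  }
  fc <- gtgo:::model_forward_cache(p, cfg, data$X, data$A_hat, data$Hseq)
  dLogit <- (fc$S - data$Y) / (n * M)
  g <- gtgo:::model_backward(p, cfg, fc, data$X, data$A_hat, data$Hseq,
                             dLogit)
  set.seed(4)
  h <- 1e-6
  for (nm in names(g)) {
    idx <- sample(length(g[[nm]]), min(4, length(g[[nm]])))
    for (kk in idx) {
      pp <- p; pp[[nm]][kk] <- pp[[nm]][kk] + h
      pm <- p; pm[[nm]][kk] <- pm[[nm]][kk] - h
      fd <- (loss_at(pp) - loss_at(pm)) / (2 * h)
      denom <- max(1e-6, abs(fd), abs(g[[nm]][kk]))
      expect_lt(abs(fd - g[[nm]][kk]) / denom, 1e-4)
    }
  }
})

test_that("increasing a true pair's logit never increases the loss", {
  set.seed(5)
  for (i in 1:25) {
    B <- sample(2:4, 1); M <- sample(2:5, 1)
    Y <- matrix(rbinom(B * M, 1, 0.5), B, M)
    logit <- matrix(rnorm(B * M), B, M)
    pos <- which(Y == 1)
    if (length(pos) == 0) next
    j <- sample(pos, 1)
    l0 <- bce_loss(Y, stats::plogis(logit))
    logit[j] <- logit[j] + runif(1, 0, 3)
    expect_lte(bce_loss(Y, stats::plogis(logit)), l0 + 1e-12)
  }
})

test_that("model_forward is consistent under row selection and id checks", {
  bundle <- tiny_bundle()
  data <- bundle$data
  tc <- training_config(hidden_d = 8, dropout = 0, seed = 2)
  model <- init_model(ncol(data$X), ncol(data$Hseq), data$terms, tc)
  all_pred <- model_forward(model, data)
  sub <- sample(data$ids, 7)
  sub_pred <- model_forward(model, data, sub)
  expect_equal(sub_pred$S, all_pred$S[sub, , drop = FALSE],
               tolerance = 1e-12)
  expect_identical(model_forward(model, data)$S, all_pred$S)
  expect_error(model_forward(model, data, c("missing1", sub)), "missing1")
})

test_that("training overfits a separable fixture and restores the best epoch", {
  bundle <- tiny_bundle()  # 60 proteins, 12 terms, noise-free
  tc <- training_config(hidden_d = 32, learning_rate = 5e-4, dropout = 0,
                        batch_size = 1024, max_epochs = 500, patience = 50,
                        seed = 1)
  fit <- train_model(bundle$data, bundle$split, tc)
  hist <- fit$history
  expect_lt(hist$train_loss[hist$best_epoch], 0.05)
  expect_lt(hist$train_loss[hist$best_epoch], hist$train_loss[1])
  pred <- model_forward(fit$model, bundle$data, bundle$split$train)
  f <- fmax(labels_for(bundle$ds, bundle$split$train), pred$S)
  expect_gte(f$fmax, 0.95)

  # restored parameters reproduce the recorded best validation loss
  va <- bundle$split$valid
  pv <- model_forward(fit$model, bundle$data, va)
  expect_equal(bce_loss(labels_for(bundle$ds, va), pv$S),
               hist$best_valid_loss, tolerance = 1e-10)
  expect_equal(hist$best_valid_loss, min(hist$valid_loss))
})

test_that("zero learning rate exhausts patience after exactly 15 flat epochs", {
  bundle <- tiny_bundle(sim_config(n_modules = 2, proteins_per_module = 6,
                                   emb_dim = 8, m_features = 10,
                                   features_per_module = 4, n_terms = 6,
                                   terms_per_module = 3, seed = 8))
  tc <- training_config(hidden_d = 6, learning_rate = 0, dropout = 0,
                        max_epochs = 1000, patience = 15, seed = 1)
  fit <- train_model(bundle$data, bundle$split, tc)
  expect_equal(fit$history$stop_reason, "patience_exhausted")
  expect_equal(length(fit$history$epoch), 16)  # epoch 1 + 15 non-improving
  expect_equal(fit$history$best_epoch, 1)
})

test_that("training is bitwise deterministic given config and seed", {
  bundle <- tiny_bundle(sim_config(n_modules = 2, proteins_per_module = 8,
                                   emb_dim = 8, m_features = 12,
                                   features_per_module = 5, n_terms = 6,
                                   terms_per_module = 3, seed = 10))
  tc <- training_config(hidden_d = 8, learning_rate = 2e-4, dropout = 0.3,
                        max_epochs = 30, patience = 15, seed = 21)
  fit1 <- train_model(bundle$data, bundle$split, tc)
  fit2 <- train_model(bundle$data, bundle$split, tc)
  expect_identical(fit1$history$train_loss, fit2$history$train_loss)
  expect_identical(fit1$history$valid_loss, fit2$history$valid_loss)
  expect_identical(fit1$model$params, fit2$model$params)
  p1 <- model_forward(fit1$model, bundle$data)
  p2 <- model_forward(fit2$model, bundle$data)
  expect_identical(p1$S, p2$S)
})

test_that("models round-trip through disk bitwise", {
  bundle <- tiny_bundle()
  tc <- training_config(hidden_d = 6, dropout = 0, seed = 4)
  model <- init_model(ncol(bundle$data$X), ncol(bundle$data$Hseq),
                      bundle$data$terms, tc)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(model, f)
  back <- load_model(f)
  expect_identical(back$params, model$params)
  expect_identical(back$config, model$config)
  expect_identical(model_forward(back, bundle$data)$S,
                   model_forward(model, bundle$data)$S)
})

test_that("single-branch configurations train and predict", {
  bundle <- tiny_bundle()
  for (br in c("ppi", "seq")) {
    tc <- training_config(hidden_d = 8, learning_rate = 5e-4, dropout = 0,
                          max_epochs = 20, patience = 15, seed = 1,
                          branches = br)
    fit <- train_model(bundle$data, bundle$split, tc)
    pred <- model_forward(fit$model, bundle$data, bundle$split$test)
    expect_true(all(pred$S >= 0 & pred$S <= 1))
    expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  }
})
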