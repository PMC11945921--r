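test_that("relu and squash obey their defining identities", {
  expect_equal(relu(c(-1, 0, 2)), c(0, 0, 2))
  expect_equal(relu(c(-5, -1)), c(0, 0))
  x <- rnorm(20)
  expect_equal(relu(relu(x)), relu(x))

  expect_equal(squash(rep(0, 8)), rep(0, 8))
  set.seed(2)
  for (i in 1:25) {
    s <- rnorm(sample(2:16, 1)) * 10^runif(1, -2, 2)
    v <- squash(s)
    n <- sqrt(sum(s^2))
    expect_lt(abs(sqrt(sum(v^2)) - n^2 / (1 + n^2)), 1e-12)
    expect_lt(sqrt(sum(v^2)), 1)
  }
  u <- c(1, 0, 0)
  expect_equal(sqrt(sum(squash(u)^2)), 0.5, tolerance = 1e-12)
  expect_gt(sqrt(sum(squash(1e3 * u)^2)), 0.999)
})

test_that("dynamic routing conserves coupling mass and matches oracles", {
  set.seed(3)
  U1 <- array(rnorm(4 * 7 * 1), c(4, 7, 1))
  r1 <- dynamic_routing(U1, iters = 3)
  expect_equal(as.numeric(r1$coupling), rep(1, 7))

  U <- array(rnorm(4 * 6 * 3), c(4, 6, 3))
  for (it in 1:4) {
    r <- dynamic_routing(U, iters = it)
    expect_equal(rowSums(r$coupling), rep(1, 6), tolerance = 1e-12)
  }

  # single iteration: uniform coupling, v_r = squash(mean prediction sum)
  r <- dynamic_routing(U, iters = 1)
  expect_equal(r$coupling, matrix(1 / 3, 6, 3), tolerance = 1e-15)
  oracle <- sapply(1:3, function(rr) squash(rowSums(U[, , rr]) / 3))
  expect_equal(r$v, oracle, tolerance = 1e-12)

  expect_error(dynamic_routing(U, iters = 0), "positive")
})

test_that("normalisation chain places samples on the unit sphere", {
  set.seed(4)
  m <- matrix(rnorm(40), 8, 5)
  R <- row_normalize(m)
  expect_true(all(abs(sqrt(rowSums(R^2)) - 1) < 1e-6))
  expect_equal(row_normalize(diag(5)), diag(5) / (1 + 1e-8),
               tolerance = 1e-7)
  mz <- m
  mz[3, ] <- 0
  expect_equal(row_normalize(mz)[3, ], rep(0, 5))

  O <- column_normalize(R)
  expect_true(all(abs(sqrt(colSums(O^2)) - 1) < 1e-6))
  expect_true(all(abs(O) <= 1 + 1e-12))
  one <- matrix(c(3, 4), 2, 1)
  expect_equal(column_normalize(one), one / (5 + 1e-8), tolerance = 1e-9)
})

test_that("sparse filtering attains its analytic extremes", {
  # one-hot columns: loss = number of samples (minimum)
  M <- diag(4)[, c(1, 2, 3, 4, 2)]
  expect_equal(sparse_filtering_loss(M), 5, tolerance = 1e-6)
  # uniform columns: loss = M * sqrt(N) (maximum)
  U <- matrix(0.7, 4, 5)
  expect_equal(sparse_filtering_loss(U), 5 * 2, tolerance = 1e-6)
  # invariance to positive row rescaling
  set.seed(5)
  A <- matrix(abs(rnorm(30)) + 0.5, 6, 5)
  A2 <- A
  A2[2, ] <- 13 * A2[2, ]
  expect_equal(sparse_filtering_loss(A), sparse_filtering_loss(A2),
               tolerance = 1e-5)
})

test_that("the sparse-filtering gradient matches finite differences", {
  set.seed(6)
  for (rep in 1:3) {
    # entries bounded away from zero keep the check clear of the |.| kinks
    Fm <- matrix(sign(rnorm(30)) * runif(30, 0.3, 1.5), 6, 5)
    g <- sparse_filtering_grad(Fm)
    h <- 1e-6
    fd <- Fm * 0
    for (i in seq_along(Fm)) {
      up <- Fm; up[i] <- up[i] + h
      dn <- Fm; dn[i] <- dn[i] - h
      fd[i] <- (sparse_filtering_loss(up) - sparse_filtering_loss(dn)) /
        (2 * h)
    }
    expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-4)
  }
  # first-order descent on the objective: decreasing within a 1% per-step
  # tolerance (the fixed step can graze |.| kinks) and overall
  Fm <- matrix(rnorm(30), 6, 5)
  losses <- numeric(50)
  for (k in 1:50) {
    losses[k] <- sparse_filtering_loss(Fm)
    Fm <- Fm - 0.01 * sparse_filtering_grad(Fm)
  }
  expect_true(all(losses[-1] <= 1.01 * losses[-50]))
  expect_lt(losses[50], losses[1])
})

test_that("self-attention is a residual softmax mixer over positions", {
  set.seed(7)
  X <- matrix(rnorm(24), 6, 4)                 # positions x channels
  out <- self_attention(X)
  Aw <- attr(out, "weights")
  expect_equal(rowSums(Aw), rep(1, 6), tolerance = 1e-12)

  Wv <- matrix(rnorm(16), 4, 4)
  x1 <- matrix(rnorm(4), 1, 4)
  o1 <- self_attention(x1, Wv = Wv)
  expect_equal(unclass(o1)[1, ], as.numeric(x1 %*% Wv + x1),
               tolerance = 1e-12, ignore_attr = TRUE)

  # permutation equivariance (no positional encoding)
  perm <- sample(6)
  o <- self_attention(X)
  op <- self_attention(X[perm, ])
  expect_equal(unclass(op), unclass(o)[perm, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("capsule trunk geometry follows the convolution arithmetic", {
  cfg <- model_config(conv_channels = 32, primary_maps = 8)
  suppressMessages(m <- build_dscnet(cfg, input_len = 1700, seed = 1))
  expect_equal(m$p1, 1692)
  expect_equal(m$p2, 842)
  expect_equal(m$p2 * cfg$primary_maps, 6736)

  dat <- tiny_model_data()
  suppressMessages(tm <- build_dscnet(tiny_config(), input_len = 256,
                                      seed = 2))
  fw <- ppgcaps:::forward_dscnet(tm, dat$x[, , 1:4, drop = FALSE],
                                 dat$fv[, 1:4, drop = FALSE])
  expect_length(fw$yhat, 4)
  expect_true(all(is.finite(fw$yhat)))

  suppressMessages(tm2 <- build_dscnet(tiny_config(), input_len = 256,
                                       seed = 2))
  fw2 <- ppgcaps:::forward_dscnet(tm2, dat$x[, , 1:4, drop = FALSE],
                                  dat$fv[, 1:4, drop = FALSE])
  expect_identical(fw$yhat, fw2$yhat)

  expect_error(suppressMessages(build_dscnet(cfg, input_len = 12)),
               "too short")
})

test_that("the fused capsule layer equals explicit per-capsule routing", {
  set.seed(8)
  cdim <- 4; P <- 5; maps <- 2; B <- 3; Dh <- 6; R <- 3
  u <- array(rnorm(cdim * P * maps * B), c(cdim, P, maps, B))
  W <- array(rnorm(Dh * cdim * maps * R), c(Dh, cdim, maps, R))
  fused <- ppgcaps:::caps_digit_fwd_cpp(u, W, cdim, P, maps, B, Dh, R, 3)
  U <- array(0, c(Dh, P * maps, R, B))
  for (b in 1:B) for (r in 1:R) for (m in 1:maps) for (p in 1:P) {
    U[, (m - 1) * P + p, r, b] <- W[, , m, r] %*% u[, p, m, b]
  }
  ref <- dynamic_routing(U, iters = 3)
  expect_equal(fused$v, ref$v, tolerance = 1e-12)
  expect_equal(array(fused$C, c(P * maps, R, B)), ref$coupling,
               tolerance = 1e-12)
})

test_that("backpropagated gradients match finite differences", {
  set.seed(9)
  len <- 64
  # one routing iteration makes the coupling coefficients constant, so the
  # stop-gradient backward pass is the exact gradient of the loss
  cfg <- model_config(conv_channels = 4, primary_maps = 2,
                      primary_capsule_dim = 4, digit_capsules = 2,
                      digit_capsule_dim = 6, dense_width = 8,
                      dropout_rate = 0, routing_iters = 1)
  suppressMessages(m <- build_dscnet(cfg, input_len = len, seed = 9))
  B <- 2
  x <- array(rnorm(len * B), c(1, len, B))
  fv <- matrix(rnorm(36 * B), 36, B)
  y <- rnorm(B)
  loss_fn <- function(mm) {
    fw <- ppgcaps:::forward_dscnet(mm, x, fv, train = FALSE)
    mean((fw$yhat - y)^2)
  }
  fw <- ppgcaps:::forward_dscnet(m, x, fv, train = TRUE)
  bw <- ppgcaps:::backward_dscnet(m, fw, 2 * (fw$yhat - y) / B)
  h <- 1e-5
  for (layer in c("conv1", "conv2", "digit", "dense1", "dense2")) {
    W <- m$params[[layer]]$W
    g <- bw$grads[[layer]]$W
    ii <- sample(length(W), 4)
    for (i in ii) {
      mp <- m; mp$params[[layer]]$W[i] <- W[i] + h
      mn <- m; mn$params[[layer]]$W[i] <- W[i] - h
      fd <- (loss_fn(mp) - loss_fn(mn)) / (2 * h)
      expect_equal(g[i], fd, tolerance = 1e-4,
                   label = paste("grad", layer, i))
    }
  }
})

test_that("the CNN baseline follows the four-block pooling stack", {
  cfg <- model_config()
  suppressMessages(m <- build_cnn_baseline(cfg, input_len = 1700, seed = 1))
  expect_equal(m$lens, c(850, 425, 212, 106))

  suppressMessages(ma <- build_cnn_baseline(cfg, attention = TRUE,
                                            input_len = 1700, seed = 1))
  attn_params <- sum(3 * cfg$num_filters[1:4]^2)
  expect_equal(ma$n_params - m$n_params, attn_params)

  dat <- tiny_model_data()
  suppressMessages(tm <- build_cnn_baseline(tiny_config(), input_len = 256,
                                            seed = 3))
  fw <- ppgcaps:::forward_cnn(tm, dat$x[, , 1:3, drop = FALSE])
  expect_length(fw$yhat, 3)
})

test_that("training overfits a tiny set and is seed-reproducible", {
  dat <- tiny_model_data(n_subjects = 4, len = 256, seed = 5)
  suppressMessages(m <- build_dscnet(tiny_config(), input_len = 256,
                                     seed = 11))
  tc <- train_config(epochs = 120, batch_size = 8, sf_weight = 0,
                     patience = 200, val_fraction = 0, seed = 11)
  fit <- train_model(m, dat$x, dat$y, fv = dat$fv, tc = tc)
  expect_lt(tail(fit$history$train_rmse, 1), 0.5)

  suppressMessages(m2 <- build_dscnet(tiny_config(), input_len = 256,
                                      seed = 11))
  fit2 <- train_model(m2, dat$x, dat$y, fv = dat$fv, tc = tc)
  expect_identical(fit$history, fit2$history)

  pred <- predict_bgl(fit$model, dat$x, fv = dat$fv)
  expect_length(pred, dim(dat$x)[3])
  perm <- sample(dim(dat$x)[3])
  pred_perm <- predict_bgl(fit$model, dat$x[, , perm, drop = FALSE],
                           fv = dat$fv[, perm, drop = FALSE])
  expect_equal(pred_perm, pred[perm], tolerance = 1e-12)
})

test_that("sparse-filtering training modes record the objective", {
  dat <- tiny_model_data(n_subjects = 6, len = 256, seed = 6)
  for (mode in c("joint", "alternating")) {
    suppressMessages(m <- build_dscnet(tiny_config(), input_len = 256,
                                       seed = 12))
    tc <- train_config(epochs = 6, batch_size = 8, sf_weight = 1e-2,
                       sf_mode = mode, sf_every = 2, patience = 20,
                       seed = 12)
    fit <- train_model(m, dat$x, dat$y, fv = dat$fv, tc = tc)
    expect_true(all(is.finite(fit$history$sf_loss)))
    expect_true(fit$model$trained)
  }
})

test_that("prediction validates inputs and clamps to physiology", {
  dat <- tiny_model_data(n_subjects = 4, len = 256, seed = 5)
  suppressMessages(m <- build_dscnet(tiny_config(), input_len = 256,
                                     seed = 1))
  expect_error(predict_bgl(m, dat$x, fv = dat$fv), "not been trained")
  tc <- train_config(epochs = 2, batch_size = 8, patience = 5, seed = 1)
  fit <- train_model(m, dat$x, dat$y, fv = dat$fv, tc = tc)
  expect_error(predict_bgl(fit$model, dat$x[, 1:100, , drop = FALSE],
                           fv = dat$fv), "must be")
  expect_error(predict_bgl(fit$model, dat$x), "feature matrix")
  # force absurd normalisation to trigger the physiological clamp
  fit$model$norms$y_center <- 100
  expect_warning(predict_bgl(fit$model, dat$x, fv = dat$fv), "clamped")
})

test_that("model checkpoints round-trip through disk", {
  dat <- tiny_model_data(n_subjects = 4, len = 256, seed = 5)
  suppressMessages(m <- build_dscnet(tiny_config(), input_len = 256,
                                     seed = 2))
  fit <- train_model(m, dat$x, dat$y, fv = dat$fv,
                     tc = train_config(epochs = 2, batch_size = 8,
                                       patience = 5, seed = 2))
  path <- tempfile(fileext = ".ckpt")
  save_model(fit$model, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_model(path)
  expect_equal(predict_bgl(back, dat$x, fv = dat$fv),
               predict_bgl(fit$model, dat$x, fv = dat$fv),
               tolerance = 1e-15)
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(sidecar$n_params, fit$model$n_params)
})
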