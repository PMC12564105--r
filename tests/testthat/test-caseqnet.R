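# CA-SeqNet: architecture contracts, gradient correctness, attention
# properties, training behavior, determinism.

test_that("the seven pooling stages reduce 10,000 samples to 78 steps", {
  cfg <- ca_seqnet_config(input_length = 10000)
  expect_equal(cfg$stage_lengths,
               c(5000L, 2500L, 1250L, 625L, 312L, 156L, 78L))
  expect_equal(cfg$flat_dim, 256L * 78L)
  expect_error(ca_seqnet_config(input_length = 100), "too short")
  expect_error(ca_seqnet_config(conv_channels = c(8, 8, 8)), "seven")
  expect_error(ca_seqnet_config(n_classes = 2), "3")
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- ca_seqnet_config(input_length = 256,
                          conv_channels = c(3, 3, 4, 4, 5, 5, 6),
                          frd_hidden = c(10, 6), dropout_rate = 0)
  model <- ca_seqnet_init(cfg, seed = 1)
  set.seed(2)
  X <- matrix(stats::rnorm(4 * 256), 4)
  y <- c(0L, 1L, 2L, 1L)
  xm <- opmclean:::as_input_matrix(X)
  res <- opmclean:::nn_loss_and_grads(model, xm, 4L, y, training = TRUE)
  h <- 1e-5
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      m2 <- model
      m2$params[[nm]][i] <- p[i] + h
      lp <- opmclean:::nn_loss_and_grads(m2, xm, 4L, y, TRUE)$loss
      m2$params[[nm]][i] <- p[i] - h
      lm <- opmclean:::nn_loss_and_grads(m2, xm, 4L, y, TRUE)$loss
      num <- (lp - lm) / (2 * h)
      ana <- res$grads[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4,
                label = sprintf("gradient of %s[%d]", nm, i))
    }
  }
})

test_that("the compiled backbone stage agrees with the plain-R reference layers", {
  set.seed(3)
  C_in <- 3L; C_out <- 5L; L <- 20L; B <- 2L; K <- 3L
  x <- matrix(stats::rnorm(C_in * L * B), C_in)
  W <- matrix(stats::rnorm(C_out * C_in * K) * 0.3, C_out)
  gamma <- stats::runif(C_out, 0.5, 1.5)
  beta <- stats::rnorm(C_out, 0, 0.2)
  st <- opmclean:::cpp_cbr_pool_forward(x, W, gamma, beta,
                                        rep(0, C_out), rep(1, C_out),
                                        L, B, K, TRUE, 0.1, 1e-5)
  # reference: R conv (tap-stacked) -> bn -> relu -> pool
  cv <- opmclean:::conv1d_forward(x, L, B, W, C_in, K)
  bn <- opmclean:::bn_forward(cv$out, gamma, beta,
                              list(mean = rep(0, C_out), var = rep(1, C_out)),
                              training = TRUE)
  relu <- bn$out * ((bn$out > 0) * 1)
  mp <- opmclean:::maxpool_forward(relu, L, B)
  expect_equal(st$out, mp$out, tolerance = 1e-10)
  expect_equal(as.numeric(st$mean), bn$state$mean, tolerance = 1e-10)
  expect_equal(as.numeric(st$var), bn$state$var, tolerance = 1e-10)

  dy <- matrix(stats::rnorm(length(mp$out)), nrow(mp$out))
  bk <- opmclean:::cpp_cbr_pool_backward(dy, st$Xstk, W, gamma, beta,
                                         st$xhat, st$invstd, st$arg, L, B, K)
  dh <- opmclean:::maxpool_backward(mp$cache, dy)
  dh <- dh * ((bn$out > 0) * 1)
  bnb <- opmclean:::bn_backward(bn$cache, dh)
  cvb <- opmclean:::conv1d_backward(cv$cache, L, B, W, C_in, K, bnb$dx)
  expect_equal(bk$dx, cvb$dx, tolerance = 1e-8)
  expect_equal(bk$dW, cvb$dW, tolerance = 1e-8)
  expect_equal(as.numeric(bk$dgamma), bnb$dgamma, tolerance = 1e-8)
  expect_equal(as.numeric(bk$dbeta), bnb$dbeta, tolerance = 1e-8)
})

test_that("channel attention gates without changing shape and stays in (0,1)", {
  set.seed(4)
  f <- matrix(stats::rnorm(12 * 30), 12)
  W <- matrix(stats::rnorm(12 * 24) * 0.2, 12)
  b <- stats::rnorm(12, 0, 0.3)
  res <- channel_attention(f, W, b)
  expect_equal(dim(res$out), dim(f))
  expect_true(all(res$weights > 0 & res$weights < 1))
  expect_true(all(abs(res$out) <= abs(f) + 1e-12))

  # saturating pre-activations leave the feature map untouched
  sat <- channel_attention(f, 0 * W, rep(40, 12))
  expect_equal(sat$out, f, tolerance = 1e-12)
})

test_that("forward produces normalized, deterministic probabilities", {
  cfg <- toy_net_config()
  model <- ca_seqnet_init(cfg, seed = 42)
  set.seed(5)
  X <- opmclean:::standardize_rows(matrix(stats::rnorm(6 * 256), 6))
  p1 <- ca_seqnet_forward(model, X)
  expect_equal(rowSums(p1), rep(1, 6), tolerance = 1e-6)
  expect_identical(p1, ca_seqnet_forward(model, X))
  expect_error(ca_seqnet_forward(model, X[, 1:100]), "samples")

  # zeroed final layer is the uniform predictor: loss = ln 3
  model$params$fc3_W[] <- 0
  model$params$fc3_b[] <- 0
  probs <- ca_seqnet_forward(model, X)
  expect_equal(probs, matrix(1 / 3, 6, 3, dimnames = dimnames(probs)),
               tolerance = 1e-12)
  expect_equal(opmclean:::cross_entropy(t(probs), rep(0:2, 2)), log(3),
               tolerance = 1e-12)
})

test_that("training reduces the loss and fits a separable toy problem", {
  ds <- augment_invert(toy_dataset(n_per = 15))
  model <- ca_seqnet_train(ds, config = toy_net_config(),
                           tc = train_config(epochs = 6, seed = 42))
  expect_lt(model$history$loss[6], model$history$loss[1])
  expect_lt(model$history$loss[6], log(3))
  pred <- ca_seqnet_predict(model, ds$waveforms)
  expect_equal(mean(pred == ds$labels), 1)

  # augmentation symmetry: a waveform and its sign-flip share the label
  flip <- ca_seqnet_predict(model, -ds$waveforms)
  expect_gte(mean(flip == pred), 0.95)
})

test_that("training is bit-reproducible under a fixed seed", {
  ds <- toy_dataset(n_per = 8, seed = 3)
  tc <- train_config(epochs = 2, seed = 42)
  m1 <- ca_seqnet_train(ds, config = toy_net_config(), tc = tc)
  m2 <- ca_seqnet_train(ds, config = toy_net_config(), tc = tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  set.seed(6)
  X <- matrix(stats::rnorm(4 * 256), 4)
  expect_identical(ca_seqnet_predict(m1, X), ca_seqnet_predict(m2, X))
})
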