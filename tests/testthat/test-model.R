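test_that("closed-form parameter counts match the published component sizes", {
  pc <- count_parameters(model_config("reference"))
  expect_identical(pc$bi_convlstm3d, 1050624)
  expect_identical(pc$attention3d, 66112)
})

test_that("count formulas equal enumerated weights for random configs", {
  set.seed(21)
  for (i in 1:20) {
    hid <- sample(c(2, 4, 8), 1)
    red <- sample(c(1, 2, 4), 1)
    cfg <- model_config("small",
                        p3d_channels = sample(2:6, 6, replace = TRUE),
                        convlstm_hidden = hid,
                        attention_reduction = red,
                        head_hidden = sample(2:8, 1),
                        peephole = sample(c(TRUE, FALSE), 1))
    m <- build_model(cfg)
    pc <- count_parameters(cfg)
    pci <- count_parameters_instantiated(m)
    expect_identical(pc[c("p3d", "bi_convlstm3d", "attention3d", "head")],
                     pci)
  }
})

test_that("a trivial 1x1x1 convolution counts two parameters", {
  l <- p3dseize:::conv3d_layer(c(1, 1, 1), c(1, 1, 1), 1, 1)
  expect_equal(p3dseize:::n_layer_params(list(l)), 2)
})

lin_conv <- function(x, kern) {
  l <- p3dseize:::conv3d_layer(dim(x)[1:3], dim(kern)[1:3], dim(kern)[4],
                               dim(kern)[5])
  p3dseize:::conv3d_set_kernel(l, kern)
  f <- p3dseize:::conv3d_forward(l, p3dseize:::arr_to_mat(x), 1)
  p3dseize:::mat_to_arr(f$y, dim(x)[1:3])
}

test_that("an identity-centred spatial kernel reproduces its input", {
  set.seed(22)
  x <- array(rnorm(3 * 4 * 7), c(3, 4, 7, 1))
  ki <- array(0, c(1, 3, 3, 1, 1)); ki[1, 2, 2, 1, 1] <- 1
  expect_equal(lin_conv(x, ki), x, tolerance = 1e-12)
})

test_that("factorised spatial+feature convolutions equal the separable 3D kernel", {
  set.seed(23)
  for (i in 1:5) {
    x <- array(rnorm(3 * 4 * 7), c(3, 4, 7, 1))
    ws <- array(rnorm(9), c(1, 3, 3, 1, 1))
    wf <- array(rnorm(3), c(3, 1, 1, 1, 1))
    y_fact <- lin_conv(lin_conv(x, ws), wf)
    k3 <- array(0, c(3, 3, 3, 1, 1))
    for (d in 1:3) k3[d, , , 1, 1] <- wf[d, 1, 1, 1, 1] * ws[1, , , 1, 1]
    y_full <- lin_conv(x, k3)
    expect_lt(max(abs(y_fact - y_full)), 1e-6)
  }
})

test_that("the reference P3D stack maps 3x4x7x1 to 3x4x7x256", {
  m <- build_model(model_config("reference"))
  x <- array(rnorm(3 * 4 * 7), c(3, 4, 7, 1))
  y <- p3d_block_forward(x, m)
  expect_equal(dim(y), c(3, 4, 7, 256))
})

test_that("a zero-weight ConvLSTM3D cell yields zero state", {
  w <- convlstm3d_weights(c(2, 2, 2), 2, 3)
  w$conv_x$W[] <- 0; w$conv_x$b[] <- 0; w$conv_h$W[] <- 0
  st <- convlstm3d_step(array(rnorm(16), c(2, 2, 2, 2)), NULL, w)
  expect_true(all(st$H == 0))
  expect_true(all(st$C == 0))
  expect_true(all(st$gates$o == 0.5))
})

test_that("a saturated forget gate carries the cell state through", {
  w <- convlstm3d_weights(c(1, 1, 1), 1, 1)
  w$conv_x$W[] <- 0; w$conv_h$W[] <- 0
  w$conv_x$b <- c(-10, 10, 0, 0)   # b_i = -10, b_f = +10
  st0 <- convlstm3d_zero_state(w, 1)
  st0$C[] <- 0.7
  st1 <- convlstm3d_step(array(1, c(1, 1, 1, 1)), st0, w)
  expect_equal(st1$C[1, 1], plogis(10) * 0.7, tolerance = 1e-9)
  expect_lt(abs(st1$C[1, 1] - 0.7), 1e-3)
})

test_that("the cell reduces exactly to a scalar LSTM on a 1x1x1 grid", {
  set.seed(24)
  w <- convlstm3d_weights(c(1, 1, 1), 1, 1)
  xs <- rnorm(10)
  st <- convlstm3d_zero_state(w, 1)
  for (xt in xs) st <- convlstm3d_step(array(xt, c(1, 1, 1, 1)), st, w)
  oracle <- oracle_scalar_lstm(xs, w$conv_x$W[1, ], w$conv_h$W[1, ],
                               w$conv_x$b)
  expect_lt(abs(st$H[1, 1] - oracle["h"]), 1e-12)
  expect_lt(abs(st$C[1, 1] - oracle["c"]), 1e-12)
})

test_that("gates always lie in their codomains", {
  set.seed(25)
  w <- convlstm3d_weights(c(2, 3, 2), 2, 4)
  st <- NULL
  for (t in 1:3) {
    st <- convlstm3d_step(array(rnorm(24, sd = 3), c(2, 3, 2, 2)), st, w)
    for (g in c("i", "f", "o")) {
      expect_true(all(st$gates[[g]] > 0 & st$gates[[g]] < 1))
    }
    expect_true(all(st$gates$g > -1 & st$gates$g < 1))
  }
})

test_that("bidirectional output concatenates and respects direction symmetry", {
  set.seed(26)
  w1 <- convlstm3d_weights(c(2, 2, 2), 2, 3)
  w2 <- convlstm3d_weights(c(2, 2, 2), 2, 3)
  seqs <- lapply(1:2, function(t) array(rnorm(16), c(2, 2, 2, 2)))
  y <- bi_convlstm3d_forward(seqs, w1, w2)
  expect_equal(dim(y), c(2, 2, 2, 6))
  # reversing the sequence and swapping directions swaps the channel halves
  y_rev <- bi_convlstm3d_forward(rev(seqs), w2, w1)
  expect_equal(y[, , , 1:3], y_rev[, , , 4:6], tolerance = 1e-12)
  expect_equal(y[, , , 4:6], y_rev[, , , 1:3], tolerance = 1e-12)
  # zero weights in both directions give zeros
  for (w in list(w1, w2)) { w$conv_x$W[] <- 0; w$conv_x$b[] <- 0; w$conv_h$W[] <- 0 }
  expect_true(all(bi_convlstm3d_forward(seqs, w1, w2) == 0))
  expect_error(bi_convlstm3d_forward(list(), w1, w2), "empty")
})

test_that("reference bidirectional hidden concatenation is 512 channels", {
  cfg <- model_config("reference")
  m <- build_model(cfg)
  expect_equal(4 * 256 * 2, ncol(m$lstm_fwd$conv_x$W) + ncol(m$lstm_bwd$conv_x$W))
  expect_equal(cfg$attention_channels, 512)
})

test_that("attention with unit excitation is the identity and squeezes means", {
  set.seed(27)
  w <- se_weights(4, 2)
  x <- array(rnorm(2 * 2 * 2 * 4), c(2, 2, 2, 4))
  # force the excitation to output ~1 for every channel
  w$fc1$W[] <- 0; w$fc1$b[] <- 0; w$fc2$W[] <- 0; w$fc2$b[] <- 50
  expect_equal(se_attention3d(x, w), x, tolerance = 1e-9)
  # a constant channel squeezes to exactly its value
  x[, , , 2] <- 3.25
  X <- p3dseize:::arr_to_mat(x)
  z <- rowsum(X, rep(1, nrow(X))) / nrow(X)
  expect_equal(unname(z[1, 2]), 3.25)
})

test_that("attention weights are sigmoidal and contract channel norms", {
  set.seed(28)
  w <- se_weights(6, 3)
  x <- array(rnorm(3 * 2 * 2 * 6, sd = 2), c(3, 2, 2, 6))
  s <- se_channel_weights(x, w)
  expect_true(all(s > 0 & s < 1))
  y <- se_attention3d(x, w)
  for (ch in 1:6) {
    expect_lte(sqrt(sum(y[, , , ch]^2)), sqrt(sum(x[, , , ch]^2)))
  }
  expect_error(se_weights(5, 2), "divisible")
})

test_that("model probabilities are a stable softmax over two classes", {
  cfg <- tiny_model_config(seed = 29)
  m <- build_model(cfg)
  x <- array(rnorm(2 * 3 * 2 * 3), c(2, 3, 2, 3))
  p1 <- model_forward(m, x)
  expect_equal(dim(p1), c(1, 2))
  expect_equal(sum(p1), 1, tolerance = 1e-6)
  expect_identical(p1, model_forward(m, x))   # inference is bit-stable
  expect_error(model_forward(m, array(0, c(2, 2, 2, 2))), "shape")
})

test_that("the model is sensitive to time-step order", {
  set.seed(30)
  hits <- 0
  for (i in 1:10) {
    # wide enough head that no random draw is fully ReLU-dead
    cfg <- model_config("small", grid_shape = c(3, 2, 3), dropout = 0,
                        seed = 100 + i)
    m <- build_model(cfg)
    x <- array(rnorm(2 * 3 * 2 * 3), c(2, 3, 2, 3))
    xr <- x[2:1, , , ]
    if (max(abs(model_forward(m, x) - model_forward(m, xr))) > 1e-9) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 9)
})

test_that("analytic gradients match finite differences through the whole network", {
  cfg <- tiny_model_config(seed = 5)
  m <- build_model(cfg)
  layers <- p3dseize:::model_layers(m)
  set.seed(31)
  # nudge biases off zero so no ReLU sits exactly at its kink
  for (l in layers) if (!is.null(l$b)) l$b <- l$b + rnorm(length(l$b), 0, 0.05)
  set.seed(9)
  x <- array(rnorm(2 * 2 * 3 * 2 * 3), c(2, 2, 3, 2, 3))
  y <- c(0L, 1L)
  p3dseize:::zero_grads(layers)
  out <- p3dseize:::model_forward_batch(m, x, train = TRUE, keep = TRUE)
  p3dseize:::model_backward_batch(m, out$probs, y, out$cache)
  loss_at <- function() {
    o <- p3dseize:::model_forward_batch(m, x, train = TRUE)
    -mean(log(o$probs[cbind(1:2, y + 1)]))
  }
  eps <- 1e-5; worst <- 0
  set.seed(11)
  for (l in layers) for (p in p3dseize:::layer_params(l)) {
    W <- get(p, envir = l); G <- get(p3dseize:::layer_grad_name(p), envir = l)
    for (rep in 1:4) {
      i <- sample(length(W), 1); W0 <- W[i]
      W[i] <- W0 + eps; assign(p, W, envir = l); lp <- loss_at()
      W[i] <- W0 - eps; assign(p, W, envir = l); lm <- loss_at()
      W[i] <- W0; assign(p, W, envir = l)
      num <- (lp - lm) / (2 * eps)
      if (abs(num) + abs(G[i]) > 1e-8) {
        worst <- max(worst, abs(num - G[i]) / (abs(num) + abs(G[i])))
      }
    }
  }
  expect_lt(worst, 1e-3)
})

test_that("training is seed-deterministic and drives the loss down", {
  ts <- fixture_tensor_set(n = 60, shift = 1.2)
  cfg <- model_config("small", epochs = 3, seed = 32)
  m1 <- train_model(ts, cfg)
  m2 <- train_model(ts, cfg)
  expect_identical(m1$history, m2$history)
  init <- build_model(cfg)
  expect_lt(m1$history$loss[2], model_loss(init, ts))
  expect_gt(m1$history$accuracy[3], 0.8)
})

test_that("training a strongly separated set reaches high accuracy", {
  ts <- fixture_tensor_set(n = 100, shift = 1.5, seed = 6)
  cfg <- model_config("small", epochs = 10, seed = 33)
  m <- train_model(ts, cfg)
  expect_gte(m$history$accuracy[10], 0.95)
})

test_that("single-class training data are rejected", {
  ts <- fixture_tensor_set(n = 20)
  ts$labels <- rep(1L, 20)
  expect_error(train_model(ts, model_config("small", epochs = 1)),
               "both classes")
})
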