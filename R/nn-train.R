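# Full network: time-distributed pseudo-3D CNN -> bidirectional ConvLSTM3D
# -> squeeze-excitation attention -> global average pool -> dense head.
# Forward and backward passes are hand-written; the P3D stack is shared
# across the two time steps (time distribution), so its gradients accumulate
# over both.

#' Build the classifier with seeded initial weights
#'
#' @param config A [model_config()].
#' @return A `p3d_model` holding all layers and the config.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  with_seed(config$seed, {
    shape <- config$grid_shape
    p3d <- list()
    cin <- 1
    for (i in 1:6) {
      p3d[[length(p3d) + 1]] <- conv3d_layer(shape, config$p3d_kernels[[i]],
                                             cin, config$p3d_channels[i])
      cin <- config$p3d_channels[i]
      if (config$bn_after_pairs && i %% 2 == 0) {
        p3d[[length(p3d) + 1]] <- bn_layer(cin)
      }
    }
    lstm_fwd <- convlstm3d_weights(shape, cin, config$convlstm_hidden,
                                   config$convlstm_kernel, config$peephole)
    lstm_bwd <- convlstm3d_weights(shape, cin, config$convlstm_hidden,
                                   config$convlstm_kernel, config$peephole)
    att <- se_weights(config$attention_channels, config$attention_reduction)
    C <- config$attention_channels
    head1 <- dense_layer(C, config$head_hidden)
    head2 <- dense_layer(config$head_hidden, config$n_classes,
                         init_sd = sqrt(1 / config$head_hidden))
    structure(list(config = config, p3d = p3d, lstm_fwd = lstm_fwd,
                   lstm_bwd = lstm_bwd, att = att, head1 = head1,
                   head2 = head2),
              class = "p3d_model")
  })
}

# Flat list of parameterised layers.
model_layers <- function(model) {
  c(model$p3d,
    list(model$lstm_fwd$conv_x, model$lstm_fwd$conv_h,
         model$lstm_bwd$conv_x, model$lstm_bwd$conv_h,
         model$att$fc1, model$att$fc2, model$head1, model$head2))
}

#' Enumerate instantiated trainable parameters per component
#'
#' Counts actual weight-array sizes; used to cross-check the closed-form
#' [count_parameters()].
#'
#' @param model A [build_model()] result.
#' @return Named list matching [count_parameters()].
#' @export
count_parameters_instantiated <- function(model) {
  list(p3d = n_layer_params(model$p3d),
       bi_convlstm3d = n_layer_params(list(
         model$lstm_fwd$conv_x, model$lstm_fwd$conv_h,
         model$lstm_bwd$conv_x, model$lstm_bwd$conv_h)) +
         (if (model$config$peephole) 6 * model$config$convlstm_hidden else 0),
       attention3d = n_layer_params(list(model$att$fc1, model$att$fc2)),
       head = n_layer_params(list(model$head1, model$head2)))
}

# P3D stack on an activation matrix with `B` effective samples.
p3d_forward_mat <- function(model, M, B, train) {
  caches <- vector("list", length(model$p3d))
  for (i in seq_along(model$p3d)) {
    l <- model$p3d[[i]]
    if (l$type == "conv3d") {
      f <- conv3d_forward(l, M, B)
      r <- relu_forward(f$y)
      caches[[i]] <- list(conv = f$cache, relu = r$cache)
      M <- r$y
    } else {
      f <- bn_forward(l, M, train)
      caches[[i]] <- f$cache
      M <- f$y
    }
  }
  list(y = M, caches = caches)
}

p3d_backward_mat <- function(model, dM, caches) {
  for (i in rev(seq_along(model$p3d))) {
    l <- model$p3d[[i]]
    if (l$type == "conv3d") {
      dM <- relu_backward(dM, caches[[i]]$relu)
      dM <- conv3d_backward(l, dM, caches[[i]]$conv)
    } else {
      dM <- bn_backward(l, dM, caches[[i]])
    }
  }
  dM
}

#' Pseudo-3D convolution stack on one time step
#'
#' Applies the six alternating spatial/cross-feature convolutions with ReLU
#' and the configured batch normalisation (inference statistics) to a single
#' step tensor.
#'
#' @param x Array `(N, H, W, C_in)` with `C_in = 1`.
#' @param model A [build_model()] result.
#' @return Array `(N, H, W, C_out)` with the final channel count (256 for the
#'   reference preset).
#' @export
p3d_block_forward <- function(x, model) {
  M <- arr_to_mat(x)
  if (ncol(M) != 1) stopf("expected a single input channel, got %d", ncol(M))
  out <- p3d_forward_mat(model, M, 1, train = FALSE)
  mat_to_arr(out$y, dim(x)[1:3])
}

# Full forward pass on a batch array (B, T, N, H, W). Returns probabilities
# and, when `keep = TRUE`, every cache needed for the backward pass.
model_forward_batch <- function(model, x, train = FALSE, keep = FALSE,
                                dropout_mask = NULL) {
  cfg <- model$config
  d <- dim(x)
  B <- d[1]; T <- d[2]
  shape <- cfg$grid_shape
  P <- prod(shape)
  # rows: position fastest, then t, then b
  M0 <- matrix(as.vector(aperm(x, c(3, 4, 5, 2, 1))), B * T * P, 1)
  p3 <- p3d_forward_mat(model, M0, B * T, train)
  C6 <- ncol(p3$y)
  step_rows <- function(t) {
    as.vector(vapply(seq_len(B), function(b) {
      as.integer(((b - 1) * T + t - 1) * P) + seq_len(P)
    }, integer(P)))
  }
  rows_t <- lapply(seq_len(T), step_rows)
  X_steps <- lapply(rows_t, function(r) p3$y[r, , drop = FALSE])

  run_dir <- function(w, order) {
    st <- convlstm3d_zero_state(w, B)
    caches <- vector("list", length(order))
    for (k in seq_along(order)) {
      out <- convlstm_step_mat(w, X_steps[[order[k]]], st)
      st <- out$state
      caches[[k]] <- out$cache
    }
    list(H = st$H, caches = caches, order = order)
  }
  fwd <- run_dir(model$lstm_fwd, seq_len(T))
  bwd <- run_dir(model$lstm_bwd, rev(seq_len(T)))
  A <- cbind(fwd$H, bwd$H)                      # (B*P, 2*hidden)

  se <- se_forward_mat(model$att, A, B)
  grp <- rep(seq_len(B), each = P)
  g <- rowsum(se$y, grp) / P                    # global average pool (B, C)
  h1 <- dense_forward(model$head1, g)
  r1 <- relu_forward(h1$y)
  hdrop <- r1$y
  mask <- NULL
  if (train && cfg$dropout > 0) {
    mask <- dropout_mask %||%
      (matrix(stats::runif(length(hdrop)) >= cfg$dropout, nrow(hdrop)) /
         (1 - cfg$dropout))
    hdrop <- hdrop * mask
  }
  h2 <- dense_forward(model$head2, hdrop)
  probs <- softmax_rows(h2$y)
  res <- list(probs = probs)
  if (keep) {
    res$cache <- list(B = B, T = T, P = P, rows_t = rows_t, p3 = p3,
                      fwd = fwd, bwd = bwd, A = A, se = se, grp = grp,
                      h1 = h1$cache, r1 = r1$cache, mask = mask,
                      h2 = h2$cache, hdrop_in = r1$y)
  }
  res
}

# Backward from softmax cross-entropy. labels: 0/1 vector length B.
model_backward_batch <- function(model, probs, labels, cache) {
  cfg <- model$config
  B <- cache$B; T <- cache$T; P <- cache$P
  Y <- matrix(0, B, cfg$n_classes)
  Y[cbind(seq_len(B), labels + 1)] <- 1
  dlogits <- (probs - Y) / B
  dhdrop <- dense_backward(model$head2, dlogits, cache$h2)
  if (!is.null(cache$mask)) dhdrop <- dhdrop * cache$mask
  dr1 <- relu_backward(dhdrop, cache$r1)
  dg <- dense_backward(model$head1, dr1, cache$h1)
  dse <- dg[cache$grp, , drop = FALSE] / P
  dA <- se_backward_mat(model$att, dse, cache$se$cache)

  hid <- cfg$convlstm_hidden
  dX_steps <- lapply(seq_len(T), function(t) NULL)
  back_dir <- function(w, run, dH_final) {
    n <- length(run$order)
    dH <- dH_final
    dC <- dH * 0
    for (k in rev(seq_len(n))) {
      out <- convlstm_step_backward(w, dH, dC, run$caches[[k]])
      t <- run$order[k]
      dX_steps[[t]] <<- if (is.null(dX_steps[[t]])) out$dX else
        dX_steps[[t]] + out$dX
      dH <- out$dHprev
      dC <- out$dCprev
    }
  }
  back_dir(model$lstm_fwd, cache$fwd, dA[, seq_len(hid), drop = FALSE])
  back_dir(model$lstm_bwd, cache$bwd, dA[, hid + seq_len(hid), drop = FALSE])

  dM6 <- matrix(0, B * T * P, ncol(cache$p3$y))
  for (t in seq_len(T)) dM6[cache$rows_t[[t]], ] <- dX_steps[[t]]
  p3d_backward_mat(model, dM6, cache$p3$caches)
  invisible(NULL)
}

#' Class probabilities for samples
#'
#' @param model A trained or freshly built [build_model()].
#' @param x A `tensor_set`, or an array `(T, N, H, W)` (one sample) or
#'   `(B, T, N, H, W)`.
#' @return Matrix `B x 2` of class probabilities (columns: interictal,
#'   preictal); rows sum to 1.
#' @export
model_forward <- function(model, x) {
  stopifnot(inherits(model, "p3d_model"))
  if (inherits(x, "tensor_set")) x <- x$data
  if (length(dim(x)) == 4) {
    x <- array(x, c(1, dim(x)))
  }
  cfg <- model$config
  if (!all(dim(x)[3:5] == cfg$grid_shape) || dim(x)[2] != cfg$n_steps) {
    stopf("sample shape (%s) does not match config (T=%d, grid %s)",
          paste(dim(x)[-1], collapse = "x"), cfg$n_steps,
          paste(cfg$grid_shape, collapse = "x"))
  }
  model_forward_batch(model, x, train = FALSE)$probs
}

#' Train the classifier
#'
#' Minimises softmax cross-entropy with Adam under the configuration's
#' learning rate, batch size and epoch count. Shuffling, initialisation and
#' dropout all derive from `config$seed`, so identical data + config give
#' identical histories.
#'
#' @param ts A `tensor_set` with labels (both classes present).
#' @param config A [model_config()].
#' @param validation Optional `tensor_set` evaluated after each epoch.
#' @param verbose Print per-epoch progress.
#' @return A `p3d_model` with a `history` data.frame (epoch, loss, accuracy,
#'   and validation columns when supplied).
#' @export
train_model <- function(ts, config = model_config("small"),
                        validation = NULL, verbose = FALSE) {
  stopifnot(inherits(ts, "tensor_set"))
  labels <- ts$labels
  if (length(unique(labels)) < 2) stopf("training data must contain both classes")
  if (min(table(labels)) < 2) stopf("need at least 2 samples per class")
  model <- build_model(config)
  layers <- model_layers(model)
  n <- dim(ts$data)[1]
  history <- data.frame()
  with_seed(config$seed + 1L, {
    step <- 0
    for (ep in seq_len(config$epochs)) {
      idx <- sample(n)
      ep_loss <- 0; ep_correct <- 0
      for (b0 in seq(1, n, by = config$batch_size)) {
        bi <- idx[b0:min(b0 + config$batch_size - 1, n)]
        xb <- ts$data[bi, , , , , drop = FALSE]
        yb <- labels[bi]
        zero_grads(layers)
        out <- model_forward_batch(model, xb, train = TRUE, keep = TRUE)
        p <- out$probs[cbind(seq_along(bi), yb + 1)]
        ep_loss <- ep_loss - sum(log(pmax(p, 1e-12)))
        ep_correct <- ep_correct + sum(max.col(out$probs) - 1 == yb)
        model_backward_batch(model, out$probs, yb, out$cache)
        step <- step + 1
        adam_step(layers, config$lr, step)
      }
      row <- data.frame(epoch = ep, loss = ep_loss / n, accuracy = ep_correct / n)
      if (!is.null(validation)) {
        vp <- model_forward_batch(model, validation$data, train = FALSE)$probs
        row$val_loss <- -mean(log(pmax(
          vp[cbind(seq_len(nrow(vp)), validation$labels + 1)], 1e-12)))
        row$val_accuracy <- mean(max.col(vp) - 1 == validation$labels)
      }
      history <- rbind(history, row)
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f acc %.3f", ep, row$loss,
                        row$accuracy))
      }
    }
  })
  model$history <- history
  model
}

#' Mean cross-entropy loss of a model on a tensor set
#'
#' @param model A `p3d_model`.
#' @param ts A labelled `tensor_set`.
#' @return Scalar mean negative log-likelihood.
#' @export
model_loss <- function(model, ts) {
  probs <- model_forward(model, ts)
  -mean(log(pmax(probs[cbind(seq_len(nrow(probs)), ts$labels + 1)], 1e-12)))
}

#' @export
print.p3d_model <- function(x, ...) {
  pc <- count_parameters(x$config)
  cat(sprintf("<p3d_model (%s preset): %s parameters (p3d %s, bi-convlstm3d %s, attention %s, head %s)>\n",
              x$config$preset, format(pc$total, big.mark = ","),
              format(pc$p3d, big.mark = ","),
              format(pc$bi_convlstm3d, big.mark = ","),
              format(pc$attention3d, big.mark = ","),
              format(pc$head, big.mark = ",")))
  if (!is.null(x$history)) {
    h <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs; final loss %.4f, accuracy %.3f\n",
                nrow(x$history), h$loss, h$accuracy))
  }
  invisible(x)
}
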