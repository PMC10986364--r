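#' Configuration of the P3D + Bi-ConvLSTM3D + attention classifier
#'
#' The `"reference"` preset pins the published architecture: six pseudo-3D
#' convolutions with channel ladder 64-64-128-128-256-256, alternating
#' spatial (1x3x3) and cross-feature (3x1x1) kernels, batch normalisation
#' after every pair; a bidirectional 3D convolutional LSTM with 256 hidden
#' channels per direction and 1x1x1 gate kernels (no peephole); 512-channel
#' squeeze-excitation attention with reduction 8; and a 64-unit dense head.
#' The `"small"` preset shrinks every width by a factor of 8 for desk-scale
#' training while keeping the identical topology.
#'
#' @param preset `"reference"` or `"small"`.
#' @param grid_shape `(N, H, W)` of one time step (default `c(3, 4, 7)`).
#' @param n_steps Time steps per sample (default 2).
#' @param p3d_channels Six output-channel counts.
#' @param convlstm_hidden Hidden channels per LSTM direction.
#' @param convlstm_kernel Gate kernel size (default `c(1, 1, 1)`).
#' @param peephole Enable peephole connections (default FALSE).
#' @param attention_reduction Squeeze-excitation bottleneck divisor.
#' @param head_hidden Dense-head width.
#' @param dropout Dropout rate before the output layer (default 0.25).
#' @param lr,batch_size,epochs Adam learning rate, batch size, epochs.
#' @param seed Integer seed controlling initialisation and batching.
#' @return A `model_config` list. `attention_channels` is always
#'   `2 * convlstm_hidden` and must be divisible by `attention_reduction`.
#' @export
model_config <- function(preset = c("reference", "small"),
                         grid_shape = c(3, 4, 7),
                         n_steps = 2,
                         p3d_channels = NULL,
                         convlstm_hidden = NULL,
                         convlstm_kernel = c(1, 1, 1),
                         peephole = FALSE,
                         attention_reduction = NULL,
                         head_hidden = NULL,
                         dropout = 0.25,
                         lr = 1e-3, batch_size = 32, epochs = 10,
                         seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "reference") {
    p3d_channels <- p3d_channels %||% c(64, 64, 128, 128, 256, 256)
    convlstm_hidden <- convlstm_hidden %||% 256
    attention_reduction <- attention_reduction %||% 8
    head_hidden <- head_hidden %||% 64
  } else {
    p3d_channels <- p3d_channels %||% c(8, 8, 16, 16, 32, 32)
    convlstm_hidden <- convlstm_hidden %||% 16
    attention_reduction <- attention_reduction %||% 4
    head_hidden <- head_hidden %||% 16
  }
  if (length(p3d_channels) != 6) stopf("p3d_channels must have length 6")
  att_channels <- 2 * convlstm_hidden
  if (att_channels %% attention_reduction != 0) {
    stopf("attention channels (%d) must be divisible by the reduction (%d)",
          att_channels, attention_reduction)
  }
  sp <- c(1, 3, 3); ft <- c(grid_shape[1], 1, 1)
  structure(list(preset = preset, grid_shape = grid_shape, n_steps = n_steps,
                 p3d_channels = p3d_channels,
                 p3d_kernels = list(sp, ft, sp, ft, sp, ft),
                 bn_after_pairs = TRUE,
                 convlstm_hidden = convlstm_hidden,
                 convlstm_kernel = convlstm_kernel,
                 peephole = peephole,
                 attention_channels = att_channels,
                 attention_reduction = attention_reduction,
                 head_hidden = head_hidden, n_classes = 2L,
                 dropout = dropout, optimizer = "adam", lr = lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "model_config")
}

#' Trainable-parameter counts per component, from shapes alone
#'
#' Counts are computed from the configuration without instantiating weights:
#' convolutions count `prod(kernel) * c_in * c_out + c_out`, batch
#' normalisation counts its scale and shift, each ConvLSTM direction counts
#' four gates of input kernel + recurrent kernel + bias (plus three peephole
#' vectors if enabled), and the attention block counts its two biased dense
#' layers. The reference preset gives 1,050,624 for the bidirectional
#' ConvLSTM and 66,112 for the attention block.
#'
#' @param config A [model_config()].
#' @return Named list `p3d`, `bi_convlstm3d`, `attention3d`, `head`, `total`.
#' @export
count_parameters <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  cin <- 1
  p3d <- 0
  for (i in 1:6) {
    k <- prod(config$p3d_kernels[[i]])
    p3d <- p3d + k * cin * config$p3d_channels[i] + config$p3d_channels[i]
    if (config$bn_after_pairs && i %% 2 == 0) {
      p3d <- p3d + 2 * config$p3d_channels[i]
    }
    cin <- config$p3d_channels[i]
  }
  kv <- prod(config$convlstm_kernel)
  hid <- config$convlstm_hidden
  one_dir <- 4 * (kv * cin * hid + kv * hid * hid + hid) +
    if (config$peephole) 3 * hid else 0
  lstm <- 2 * one_dir
  C <- config$attention_channels
  Cr <- C / config$attention_reduction
  att <- C * Cr + Cr + Cr * C + C
  head <- C * config$head_hidden + config$head_hidden +
    config$head_hidden * config$n_classes + config$n_classes
  list(p3d = p3d, bi_convlstm3d = lstm, attention3d = att, head = head,
       total = p3d + lstm + att + head)
}

# ---- ConvLSTM3D cell --------------------------------------------------------

#' ConvLSTM3D gate weights
#'
#' Per gate (input, forget, cell, output): an input convolution kernel, a
#' recurrent convolution kernel, and a bias; optionally three peephole
#' vectors (disabled by default). The forget-gate bias is initialised to 1,
#' the usual stabilisation.
#'
#' @param grid_shape `(D, H, W)` lattice.
#' @param in_channels Input channels.
#' @param hidden Hidden channels.
#' @param kernel Gate kernel size (default `c(1, 1, 1)`).
#' @param peephole Include peephole weights.
#' @return A `convlstm3d_weights` object.
#' @export
convlstm3d_weights <- function(grid_shape, in_channels, hidden,
                               kernel = c(1, 1, 1), peephole = FALSE) {
  glorot <- sqrt(1 / (prod(kernel) * (in_channels + hidden)))
  conv_x <- conv3d_layer(grid_shape, kernel, in_channels, 4 * hidden,
                         bias = TRUE, init_sd = glorot)
  conv_h <- conv3d_layer(grid_shape, kernel, hidden, 4 * hidden,
                         bias = FALSE, init_sd = glorot)
  conv_x$b[hidden + seq_len(hidden)] <- 1   # forget-gate bias
  w <- new_layer("convlstm3d", grid_shape = grid_shape,
                 in_channels = in_channels, hidden = hidden, kernel = kernel,
                 peephole = peephole, conv_x = conv_x, conv_h = conv_h)
  if (peephole) {
    w$w_ci <- numeric(hidden); w$w_cf <- numeric(hidden)
    w$w_co <- numeric(hidden)
  }
  w
}

#' Zero initial ConvLSTM3D state
#'
#' @param w A [convlstm3d_weights()].
#' @param batch Batch size.
#' @return A `convlstm3d_state` with zero hidden/cell matrices.
#' @export
convlstm3d_zero_state <- function(w, batch = 1) {
  P <- prod(w$grid_shape)
  Z <- matrix(0, batch * P, w$hidden)
  structure(list(H = Z, C = Z, gates = NULL, batch = batch),
            class = "convlstm3d_state")
}

# Internal step on activation matrices; returns state + cache for BPTT.
convlstm_step_mat <- function(w, X, state) {
  B <- state$batch
  hid <- w$hidden
  fx <- conv3d_forward(w$conv_x, X, B)
  fh <- conv3d_forward(w$conv_h, state$H, B)
  Z <- fx$y + fh$y
  zi <- Z[, seq_len(hid), drop = FALSE]
  zf <- Z[, hid + seq_len(hid), drop = FALSE]
  zg <- Z[, 2 * hid + seq_len(hid), drop = FALSE]
  zo <- Z[, 3 * hid + seq_len(hid), drop = FALSE]
  if (w$peephole) {
    zi <- zi + sweep(state$C, 2, w$w_ci, "*")
    zf <- zf + sweep(state$C, 2, w$w_cf, "*")
  }
  i <- sigmoid(zi); f <- sigmoid(zf); g <- tanh(zg)
  Cn <- f * state$C + i * g
  if (w$peephole) zo <- zo + sweep(Cn, 2, w$w_co, "*")
  o <- sigmoid(zo)
  Hn <- o * tanh(Cn)
  st <- structure(list(H = Hn, C = Cn,
                       gates = list(i = i, f = f, o = o, g = g), batch = B),
                  class = "convlstm3d_state")
  cache <- list(X = X, Hprev = state$H, Cprev = state$C, i = i, f = f, g = g,
                o = o, Cn = Cn, fx = fx$cache, fh = fh$cache)
  list(state = st, cache = cache)
}

# Backward through one step. dH, dC: gradients flowing into H_t and C_t.
# Returns dX, dHprev, dCprev; accumulates conv grads.
convlstm_step_backward <- function(w, dH, dC, cache) {
  tC <- tanh(cache$Cn)
  do_ <- dH * tC
  dzo <- do_ * cache$o * (1 - cache$o)
  dC <- dC + dH * cache$o * (1 - tC^2)
  if (w$peephole) {
    dC <- dC + sweep(dzo, 2, w$w_co, "*")
  }
  di <- dC * cache$g
  df <- dC * cache$Cprev
  dg <- dC * cache$i
  dCprev <- dC * cache$f
  dzi <- di * cache$i * (1 - cache$i)
  dzf <- df * cache$f * (1 - cache$f)
  dzg <- dg * (1 - cache$g^2)
  if (w$peephole) {
    dCprev <- dCprev + sweep(dzi, 2, w$w_ci, "*") + sweep(dzf, 2, w$w_cf, "*")
  }
  dZ <- cbind(dzi, dzf, dzg, dzo)
  dX <- conv3d_backward(w$conv_x, dZ, cache$fx)
  dHprev <- conv3d_backward(w$conv_h, dZ, cache$fh)
  list(dX = dX, dHprev = dHprev, dCprev = dCprev)
}

#' One ConvLSTM3D step on a grid tensor
#'
#' Computes the gates `i`, `f`, `o` (sigmoid), the candidate `g` (tanh), the
#' cell update `C_t = f * C_(t-1) + i * g`, and `H_t = o * tanh(C_t)`, where
#' gate pre-activations are convolutions of the input and previous hidden
#' state (plus optional peephole terms). All products are element-wise.
#'
#' @param X_t Input array `(D, H, W, in_channels)`.
#' @param state A `convlstm3d_state` (use [convlstm3d_zero_state()] to
#'   start), or `NULL` for zeros.
#' @param w A [convlstm3d_weights()].
#' @return Updated `convlstm3d_state`; `$gates` holds the transient gate
#'   matrices for inspection.
#' @export
convlstm3d_step <- function(X_t, state, w) {
  stopifnot(is.environment(w), identical(w$type, "convlstm3d"))
  X <- arr_to_mat(X_t)
  if (ncol(X) != w$in_channels) {
    stopf("input has %d channels, weights expect %d", ncol(X), w$in_channels)
  }
  if (is.null(state)) state <- convlstm3d_zero_state(w, 1)
  if (!all(dim(state$H) == c(nrow(X), w$hidden))) {
    stopf("state shape mismatch: H is %dx%d, expected %dx%d",
          nrow(state$H), ncol(state$H), nrow(X), w$hidden)
  }
  convlstm_step_mat(w, X, state)$state
}

#' Bidirectional ConvLSTM3D over a step sequence
#'
#' Runs one cell forward over `t = 1..T` and another over the reversed
#' sequence, then concatenates the two final hidden states on the channel
#' axis.
#'
#' @param sequence List of T arrays `(D, H, W, C_in)`, T >= 1.
#' @param w_fwd,w_bwd [convlstm3d_weights()] for the two directions.
#' @return Array `(D, H, W, 2 * hidden)`.
#' @export
bi_convlstm3d_forward <- function(sequence, w_fwd, w_bwd) {
  if (length(sequence) < 1) stopf("empty sequence")
  run <- function(w, seq_list) {
    st <- convlstm3d_zero_state(w, 1)
    for (x in seq_list) st <- convlstm_step_mat(w, arr_to_mat(x), st)$state
    st$H
  }
  Hf <- run(w_fwd, sequence)
  Hb <- run(w_bwd, rev(sequence))
  mat_to_arr(cbind(Hf, Hb), w_fwd$grid_shape)
}

# ---- squeeze-excitation attention ------------------------------------------

#' Squeeze-excitation attention weights
#'
#' @param channels Channel count C.
#' @param reduction Bottleneck divisor (must divide C).
#' @return An `se_weights` object holding the two biased dense layers.
#' @export
se_weights <- function(channels, reduction) {
  if (channels %% reduction != 0) {
    stopf("channels (%d) not divisible by reduction (%d)", channels, reduction)
  }
  new_layer("se", channels = channels, reduction = reduction,
            fc1 = dense_layer(channels, channels / reduction),
            fc2 = dense_layer(channels / reduction, channels,
                              init_sd = sqrt(1 / (channels / reduction))))
}

# Internal: x matrix (B*P, C) -> list(y, cache).
se_forward_mat <- function(w, X, B) {
  P <- nrow(X) / B
  grp <- rep(seq_len(B), each = P)
  z <- rowsum(X, grp) / P                       # squeeze: (B, C)
  f1 <- dense_forward(w$fc1, z)
  r1 <- relu_forward(f1$y)
  f2 <- dense_forward(w$fc2, r1$y)
  s <- sigmoid(f2$y)                            # (B, C) in (0,1)
  Sbig <- s[grp, , drop = FALSE]
  list(y = X * Sbig, cache = list(X = X, s = s, Sbig = Sbig, grp = grp, P = P,
                                  f1 = f1$cache, r1 = r1$cache, f2 = f2$cache))
}

se_backward_mat <- function(w, dY, cache) {
  dX <- dY * cache$Sbig
  ds <- rowsum(dY * cache$X, cache$grp)
  df2 <- ds * cache$s * (1 - cache$s)
  dr1 <- dense_backward(w$fc2, df2, cache$f2)
  df1 <- relu_backward(dr1, cache$r1)
  dz <- dense_backward(w$fc1, df1, cache$f1)
  dX + dz[cache$grp, , drop = FALSE] / cache$P
}

#' Squeeze-excitation channel attention on a grid tensor
#'
#' Squeeze: global average over the three lattice dimensions per channel.
#' Excitation: dense C -> C/reduction (ReLU) -> C (sigmoid). Scale: each
#' channel multiplied by its weight in (0, 1), so per-channel output norms
#' never exceed input norms.
#'
#' @param x Array `(D, H, W, C)`.
#' @param w An [se_weights()].
#' @return Array of the same shape.
#' @export
se_attention3d <- function(x, w) {
  X <- arr_to_mat(x)
  if (ncol(X) != w$channels) {
    stopf("input has %d channels, attention expects %d", ncol(X), w$channels)
  }
  mat_to_arr(se_forward_mat(w, X, 1)$y, dim(x)[1:3])
}

#' Channel weights produced by the excitation branch
#'
#' @inheritParams se_attention3d
#' @return Numeric vector of C sigmoid weights in (0, 1).
#' @export
se_channel_weights <- function(x, w) {
  X <- arr_to_mat(x)
  as.vector(se_forward_mat(w, X, 1)$cache$s)
}
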