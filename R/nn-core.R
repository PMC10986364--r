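# Computational primitives for the network: 3D convolution over the
# (features x grid-rows x grid-cols) lattice, batch normalisation, dense
# layers, and their backward passes. Activations are stored as matrices with
# rows = batch * positions (position index fastest, column-major over
# (d, h, w)) and columns = channels; convolutions become gather + matrix
# multiply against precomputed neighbour indices, so all heavy lifting is
# BLAS.

# Neighbour table for same-padded convolution: P x K matrix of source
# positions (0 = outside the lattice). Kernel offsets are ordered
# column-major over (kd, kh, kw); odd kernel sizes only.
make_nbr <- function(shape, ks) {
  D <- shape[1]; H <- shape[2]; W <- shape[3]
  if (any(ks %% 2 == 0)) stopf("kernel sizes must be odd (got %s)",
                               paste(ks, collapse = "x"))
  P <- D * H * W; K <- prod(ks)
  off <- expand.grid(od = seq_len(ks[1]) - (ks[1] + 1) / 2,
                     oh = seq_len(ks[2]) - (ks[2] + 1) / 2,
                     ow = seq_len(ks[3]) - (ks[3] + 1) / 2)
  pos <- expand.grid(d = seq_len(D), h = seq_len(H), w = seq_len(W))
  nbr <- matrix(0L, P, K)
  for (q in seq_len(K)) {
    d <- pos$d + off$od[q]; h <- pos$h + off$oh[q]; w <- pos$w + off$ow[q]
    ok <- d >= 1 & d <= D & h >= 1 & h <= H & w >= 1 & w <= W
    nbr[ok, q] <- as.integer(d[ok] + (h[ok] - 1) * D + (w[ok] - 1) * D * H)
  }
  nbr
}

# Gather index for a batch: (B*P) x K into rbind(0, M); 1 = the zero row.
batch_gather_index <- function(nbr, B) {
  P <- nrow(nbr); K <- ncol(nbr)
  base <- rep((seq_len(B) - 1L) * P, each = P)
  g <- matrix(1L, B * P, K)
  for (q in seq_len(K)) {
    v <- rep(nbr[, q], B)
    ok <- v > 0L
    g[ok, q] <- v[ok] + base[ok] + 1L
  }
  g
}

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e
}

# ---- conv3d -----------------------------------------------------------------

conv3d_layer <- function(shape, ks, cin, cout, bias = TRUE,
                         init_sd = NULL) {
  K <- prod(ks)
  init_sd <- init_sd %||% sqrt(2 / (K * cin))
  W <- matrix(stats::rnorm(K * cin * cout, sd = init_sd), K * cin, cout)
  new_layer("conv3d", shape = shape, ks = ks, cin = cin, cout = cout,
            K = K, nbr = make_nbr(shape, ks), W = W,
            b = if (bias) numeric(cout) else NULL,
            gW = matrix(0, K * cin, cout),
            gb = if (bias) numeric(cout) else NULL,
            gidx_cache = list())
}

conv3d_gidx <- function(layer, B) {
  key <- as.character(B)
  g <- layer$gidx_cache[[key]]
  if (is.null(g)) {
    g <- batch_gather_index(layer$nbr, B)
    layer$gidx_cache[[key]] <- g
  }
  g
}

conv3d_forward <- function(layer, M, B) {
  gidx <- conv3d_gidx(layer, B)
  Mpad <- rbind(0, M)
  G <- matrix(0, nrow(M), layer$K * layer$cin)
  for (q in seq_len(layer$K)) {
    G[, (q - 1) * layer$cin + seq_len(layer$cin)] <- Mpad[gidx[, q], , drop = FALSE]
  }
  Y <- G %*% layer$W
  if (!is.null(layer$b)) Y <- sweep(Y, 2, layer$b, "+")
  list(y = Y, cache = list(G = G, gidx = gidx))
}

conv3d_backward <- function(layer, dY, cache) {
  layer$gW <- layer$gW + crossprod(cache$G, dY)
  if (!is.null(layer$b)) layer$gb <- layer$gb + colSums(dY)
  dG <- dY %*% t(layer$W)
  dM <- matrix(0, nrow(dY), layer$cin)
  for (q in seq_len(layer$K)) {
    src <- cache$gidx[, q]
    ok <- src > 1L
    if (any(ok)) {
      rows <- src[ok] - 1L
      dM[rows, ] <- dM[rows, , drop = FALSE] +
        dG[ok, (q - 1) * layer$cin + seq_len(layer$cin), drop = FALSE]
    }
  }
  dM
}

# Load an explicit kernel array (kd x kh x kw x cin x cout) into the layer's
# flattened weight matrix (used by tests constructing hand-built kernels).
conv3d_set_kernel <- function(layer, kernel, bias = NULL) {
  ks <- layer$ks
  stopifnot(all(dim(kernel) == c(ks, layer$cin, layer$cout)))
  W <- matrix(0, layer$K * layer$cin, layer$cout)
  for (q in seq_len(layer$K)) {
    qd <- (q - 1) %% ks[1] + 1
    qh <- ((q - 1) %/% ks[1]) %% ks[2] + 1
    qw <- (q - 1) %/% (ks[1] * ks[2]) + 1
    W[(q - 1) * layer$cin + seq_len(layer$cin), ] <-
      matrix(kernel[qd, qh, qw, , ], layer$cin, layer$cout)
  }
  layer$W <- W
  if (!is.null(layer$b)) layer$b <- bias %||% numeric(layer$cout)
  invisible(layer)
}

# ---- batch normalisation ----------------------------------------------------

bn_layer <- function(c_out, momentum = 0.1, eps = 1e-5) {
  new_layer("bn", gamma = rep(1, c_out), beta = numeric(c_out),
            run_mean = numeric(c_out), run_var = rep(1, c_out),
            momentum = momentum, eps = eps,
            ggamma = numeric(c_out), gbeta = numeric(c_out))
}

bn_forward <- function(layer, M, train) {
  if (train) {
    mu <- colMeans(M)
    xc <- sweep(M, 2, mu)
    v <- colMeans(xc * xc)
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
    layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
    xc <- sweep(M, 2, mu)
  }
  inv_sd <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(xc, 2, inv_sd, "*")
  y <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
  list(y = y, cache = list(xhat = xhat, inv_sd = inv_sd, train = train))
}

bn_backward <- function(layer, dY, cache) {
  xhat <- cache$xhat
  layer$ggamma <- layer$ggamma + colSums(dY * xhat)
  layer$gbeta <- layer$gbeta + colSums(dY)
  if (!cache$train) {
    return(sweep(dY, 2, layer$gamma * cache$inv_sd, "*"))
  }
  n <- nrow(dY)
  dxhat <- sweep(dY, 2, layer$gamma, "*")
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), "*")
  sweep(t1 - t2, 2, cache$inv_sd, "*")
}

# ---- dense ------------------------------------------------------------------

dense_layer <- function(cin, cout, init_sd = NULL) {
  init_sd <- init_sd %||% sqrt(2 / cin)
  new_layer("dense", W = matrix(stats::rnorm(cin * cout, sd = init_sd), cin, cout),
            b = numeric(cout), gW = matrix(0, cin, cout), gb = numeric(cout))
}

dense_forward <- function(layer, X) {
  list(y = sweep(X %*% layer$W, 2, layer$b, "+"), cache = list(X = X))
}

dense_backward <- function(layer, dY, cache) {
  layer$gW <- layer$gW + crossprod(cache$X, dY)
  layer$gb <- layer$gb + colSums(dY)
  dY %*% t(layer$W)
}

# ---- activations ------------------------------------------------------------

relu_forward <- function(X) {
  y <- pmax(X, 0)
  list(y = y, cache = X > 0)
}
relu_backward <- function(dY, mask) dY * mask

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# ---- parameter plumbing -----------------------------------------------------

layer_params <- function(layer) {
  switch(layer$type,
         conv3d = c("W", if (!is.null(layer$b)) "b"),
         dense = c("W", "b"),
         bn = c("gamma", "beta"),
         character(0))
}

layer_grad_name <- function(p) {
  c(W = "gW", b = "gb", gamma = "ggamma", beta = "gbeta")[[p]]
}

zero_grads <- function(layers) {
  for (l in layers) for (p in layer_params(l)) {
    g <- layer_grad_name(p)
    assign(g, get(g, envir = l) * 0, envir = l)
  }
  invisible(NULL)
}

n_layer_params <- function(layers) {
  sum(vapply(layers, function(l) {
    sum(vapply(layer_params(l), function(p) length(get(p, envir = l)), 0))
  }, 0))
}

# Adam update across a flat list of layers.
adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in layers) for (p in layer_params(l)) {
    g <- get(layer_grad_name(p), envir = l)
    mkey <- paste0("adam_m_", p); vkey <- paste0("adam_v_", p)
    m <- if (exists(mkey, envir = l)) get(mkey, envir = l) else g * 0
    v <- if (exists(vkey, envir = l)) get(vkey, envir = l) else g * 0
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    assign(p, get(p, envir = l) - lr * mh / (sqrt(vh) + eps), envir = l)
    assign(mkey, m, envir = l)
    assign(vkey, v, envir = l)
  }
  invisible(NULL)
}

# Array (D,H,W,C) <-> activation matrix (P, C).
arr_to_mat <- function(x) {
  d <- dim(x)
  matrix(as.vector(x), prod(d[1:3]), d[4])
}
mat_to_arr <- function(M, shape) array(as.vector(M), c(shape, ncol(M)))
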