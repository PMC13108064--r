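# Minimal neural-network primitives used by the multimodal classifiers:
# im2col 1D convolution, batch normalization, max pooling, inverted
# dropout, dense layers, an LSTM cell with backpropagation through time,
# softmax cross-entropy, and an Adam optimizer.
#
# Layout: channel-major. Sequence activations are arrays (C, L, B)
# (channels, positions, batch); unrolled/dense activations are matrices
# (features x columns) with columns ordered position-fastest, then batch.
# Per-channel parameters (biases, batch-norm scales) are length-C vectors
# that recycle natively down matrix columns, so no per-element expansion
# is ever materialized; all heavy arithmetic is BLAS matrix multiplies.
#
# All functions are internal; the public surface is in
# multimodal_models.R.

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

# ---- conv1d (valid padding, stride 1) --------------------------------------

im2col1d <- function(X, k) {
  # X: array (C, L, B) -> matrix (k*C, Lo*B), Lo = L - k + 1
  d <- dim(X)
  cpp_im2col(X, d[1], d[2], d[3], k)
}

col2im1d <- function(dM, k, C, L, B) {
  cpp_col2im(dM, C, L, B, k)
}

conv1d_forward <- function(X, W, b, k) {
  # W: (out_ch x k*in_ch); returns Z (out_ch x Lo*B)
  d <- dim(X)
  M <- im2col1d(X, k)
  list(Z = W %*% M + b, M = M, C = d[1], L = d[2], B = d[3],
       Lo = d[2] - k + 1L)
}

conv1d_backward <- function(dZ, cache, W, k) {
  list(dW = tcrossprod(dZ, cache$M), db = rowSums(dZ),
       dX = col2im1d(crossprod(W, dZ), k, cache$C, cache$L, cache$B))
}

# ---- batch norm (per channel = per row) ------------------------------------

bn_forward <- function(Z, gamma, beta, state, train, momentum = 0.9, eps = 1e-5) {
  if (train) {
    f <- cpp_bn_fwd(Z, gamma, beta, eps)
    state$mean <- momentum * state$mean + (1 - momentum) * f$mean
    state$var <- momentum * state$var +
      (1 - momentum) * (1 / f$inv_std^2 - eps)
    return(list(Y = f$Y, xhat = f$xhat, inv_std = f$inv_std, state = state))
  }
  inv_std <- 1 / sqrt(state$var + eps)
  xhat <- (Z - state$mean) * inv_std
  list(Y = gamma * xhat + beta, xhat = xhat, inv_std = inv_std,
       state = state)
}

bn_backward <- function(dY, cache, gamma) {
  cpp_bn_bwd(dY, cache$xhat, cache$inv_std, gamma)
}

# ---- max pool (size 2, along positions) ------------------------------------

pool2_forward <- function(X) {
  d <- dim(X)
  f <- cpp_pool2_fwd(X, d[1], d[2], d[3])
  list(Y = f$Y, mask = f$mask, C = d[1], L = d[2], B = d[3],
       Lo = d[2] %/% 2L)
}

pool2_backward <- function(dY, cache) {
  cpp_pool2_bwd(dY, cache$mask, cache$C, cache$L, cache$B)
}

# ---- dropout (inverted) ----------------------------------------------------

dropout_forward <- function(X, p, train) {
  if (!train || p <= 0) return(list(Y = X, mask = NULL))
  cpp_dropout_fwd(X, stats::runif(length(X)), p)
}

dropout_backward <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

# ---- dense (features x batch) ----------------------------------------------

dense_forward <- function(X, W, b) {
  list(Z = W %*% X + b, X = X)
}

dense_backward <- function(dZ, cache, W) {
  list(dW = tcrossprod(dZ, cache$X), db = rowSums(dZ),
       dX = crossprod(W, dZ))
}

relu <- function(x) cpp_relu(x)
drelu <- function(dy, x) cpp_drelu(dy, x)
sigm <- function(x) 1 / (1 + exp(-x))

# ---- LSTM (final hidden state as embedding) --------------------------------

lstm_init <- function(in_dim, units) {
  b <- numeric(4 * units)
  b[(units + 1):(2 * units)] <- 1  # forget-gate bias
  list(Wx = he_init(4 * units, in_dim, in_dim),
       Wh = he_init(4 * units, units, units),
       b = b)
}

lstm_forward <- function(X, Wx, Wh, b, units) {
  # X: (C, T, B); h, c: (units x B)
  d <- dim(X); C <- d[1]; Tt <- d[2]; B <- d[3]
  h <- matrix(0, units, B); cc <- matrix(0, units, B)
  i1 <- 1:units; i2 <- units + i1; i3 <- 2 * units + i1; i4 <- 3 * units + i1
  steps <- vector("list", Tt)
  for (t in seq_len(Tt)) {
    xt <- matrix(X[, t, , drop = FALSE], C, B)
    A <- Wx %*% xt + Wh %*% h + b
    i <- sigm(A[i1, , drop = FALSE])
    f <- sigm(A[i2, , drop = FALSE])
    o <- sigm(A[i3, , drop = FALSE])
    g <- tanh(A[i4, , drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    steps[[t]] <- list(xt = xt, h_prev = h, c_prev = cc,
                       i = i, f = f, o = o, g = g, tc = tc)
    cc <- c_new
    h <- o * tc
  }
  list(h = h, steps = steps, B = B, Tt = Tt, in_dim = C)
}

lstm_backward <- function(dh, cache, Wx, Wh, units) {
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(4 * units)
  dc <- matrix(0, units, cache$B)
  dX <- array(0, c(cache$in_dim, cache$Tt, cache$B))
  for (t in rev(seq_len(cache$Tt))) {
    s <- cache$steps[[t]]
    do_ <- dh * s$tc * s$o * (1 - s$o)
    dc <- dc + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g * s$i * (1 - s$i)
    df <- dc * s$c_prev * s$f * (1 - s$f)
    dg <- dc * s$i * (1 - s$g^2)
    dA <- rbind(di, df, do_, dg)
    dWx <- dWx + tcrossprod(dA, s$xt)
    dWh <- dWh + tcrossprod(dA, s$h_prev)
    db <- db + rowSums(dA)
    dX[, t, ] <- crossprod(Wx, dA)
    dh <- crossprod(Wh, dA)
    dc <- dc * s$f
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

# ---- softmax cross-entropy (classes x batch) -------------------------------

softmax_cols <- function(Z) {
  mx <- do.call(pmax, lapply(seq_len(nrow(Z)), function(i) Z[i, ]))
  E <- exp(Z - rep(mx, each = nrow(Z)))
  E / rep(colSums(E), each = nrow(Z))
}

softmax_ce <- function(Z, Y) {
  # Z, Y: (classes x batch), Y one-hot
  P <- softmax_cols(Z)
  loss <- -mean(log(pmax(colSums(P * Y), 1e-12)))
  list(loss = loss, dZ = (P - Y) / ncol(Z), P = P)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  params <- cpp_adam_step(params, grads, state$m, state$v, state$t,
                          lr, beta1, beta2, eps)
  list(params = params, state = state)
}
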