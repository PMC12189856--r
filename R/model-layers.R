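# Layer primitives for the hybrid convolutional / attention / LSTM
# classifier. Every forward function returns its output plus the cache its
# paired backward function needs; batches are stored batch-major as
# B x T x D arrays (so matrix(x, B*T, D) collapses the first two axes).
#
# Shapes are kept deliberately small (the classifier operates on a
# channels x features matrix per instance, not raw signal), so plain
# vectorized R with small per-head loops is fast enough for CPU training.

# ---- valid 1-D convolution along the second axis -------------------------

# x: B x L x Cin, W: K x Cin x Cout, b: Cout  ->  B x (L-K+1) x Cout
conv1d_forward <- function(x, W, b) {
  B <- dim(x)[1]; L <- dim(x)[2]; Cin <- dim(x)[3]
  K <- dim(W)[1]; Cout <- dim(W)[3]
  Lout <- L - K + 1L
  if (Lout < 1L) stop_validation(sprintf(
    "conv input length %d shorter than kernel %d", L, K))
  Xcol <- matrix(0, B * Lout, K * Cin)
  for (k in seq_len(K)) {
    xk <- x[, k:(k + Lout - 1L), , drop = FALSE]
    Xcol[, ((k - 1L) * Cin + 1L):(k * Cin)] <- matrix(xk, B * Lout, Cin)
  }
  Wm <- matrix(aperm(W, c(2, 1, 3)), K * Cin, Cout)  # rows: Cin fastest per k
  out <- Xcol %*% Wm
  out <- sweep(out, 2, b, "+")
  list(y = array(out, c(B, Lout, Cout)),
       cache = list(Xcol = Xcol, Wm = Wm, dims = c(B, L, Cin, K, Cout, Lout)))
}

conv1d_backward <- function(dy, cache) {
  d <- cache$dims
  B <- d[1]; L <- d[2]; Cin <- d[3]; K <- d[4]; Cout <- d[5]; Lout <- d[6]
  dym <- matrix(dy, B * Lout, Cout)
  dW <- t(cache$Xcol) %*% dym                       # (K*Cin) x Cout
  db <- colSums(dym)
  dXcol <- dym %*% t(cache$Wm)
  dx <- array(0, c(B, L, Cin))
  for (k in seq_len(K)) {
    blk <- array(dXcol[, ((k - 1L) * Cin + 1L):(k * Cin)], c(B, Lout, Cin))
    dx[, k:(k + Lout - 1L), ] <- dx[, k:(k + Lout - 1L), , drop = FALSE] + blk
  }
  dWarr <- aperm(array(dW, c(Cin, K, Cout)), c(2, 1, 3))
  list(dx = dx, dW = dWarr, db = db)
}

relu_forward <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_backward <- function(dy, cache) dy * cache

# ---- max pooling along the second axis -----------------------------------

maxpool_forward <- function(x, pool) {
  B <- dim(x)[1]; L <- dim(x)[2]; C <- dim(x)[3]
  T_ <- L %/% pool
  if (T_ < 1L) stop_validation("pooling window larger than input length")
  y <- array(-Inf, c(B, T_, C))
  arg <- array(1L, c(B, T_, C))
  for (p in seq_len(pool)) {
    cand <- x[, seq(p, by = pool, length.out = T_), , drop = FALSE]
    upd <- cand > y
    y[upd] <- cand[upd]
    arg[upd] <- p
  }
  list(y = y, cache = list(arg = arg, dims = c(B, L, C), pool = pool))
}

maxpool_backward <- function(dy, cache) {
  dims <- cache$dims
  pool <- cache$pool
  T_ <- dim(dy)[2]
  dx <- array(0, dims)
  for (p in seq_len(pool)) {
    sel <- cache$arg == p
    slice <- array(0, dim(dy))
    slice[sel] <- dy[sel]
    dx[, seq(p, by = pool, length.out = T_), ] <- slice
  }
  dx
}

# ---- batch normalization (per channel over batch x positions) ------------

batchnorm_forward <- function(x, gamma, beta, train, run_mean, run_var,
                              momentum = 0.9, eps = 1e-5) {
  B <- dim(x)[1]; T_ <- dim(x)[2]; C <- dim(x)[3]
  xm <- matrix(x, B * T_, C)
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(sweep(xm, 2, mu)^2)
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean
    v <- run_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, inv, "*")
  ym <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = array(ym, c(B, T_, C)),
       cache = list(xhat = xhat, inv = inv, gamma = gamma, dims = c(B, T_, C)),
       run_mean = run_mean, run_var = run_var)
}

batchnorm_backward <- function(dy, cache) {
  d <- cache$dims
  N <- d[1] * d[2]
  dym <- matrix(dy, N, d[3])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, cache$gamma, "*")
  # dx = inv/N * (N*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  dxm <- sweep(
    N * dxhat -
      matrix(colSums(dxhat), N, d[3], byrow = TRUE) -
      cache$xhat * matrix(colSums(dxhat * cache$xhat), N, d[3], byrow = TRUE),
    2, cache$inv / N, "*")
  list(dx = array(dxm, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- layer normalization (per position over the feature axis) ------------
# As in the residual blocks: plain standardization, no learnable affine.

layernorm_forward <- function(x, eps = 1e-8) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  mu <- rowMeans(xm)
  xc <- xm - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = array(xhat, d), cache = list(xhat = xhat, inv = inv, dims = d))
}

layernorm_backward <- function(dy, cache) {
  d <- cache$dims
  D <- d[3]
  dym <- matrix(dy, d[1] * d[2], D)
  m1 <- rowMeans(dym)
  m2 <- rowMeans(dym * cache$xhat)
  dxm <- cache$inv * (dym - m1 - cache$xhat * m2)
  array(dxm, d)
}

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

# ---- multi-head scaled dot-product self-attention ------------------------

# x: B x T x D; Wq/Wk/Wv: D x (h*dk); Wo: (h*dk) x D
attention_forward <- function(x, Wq, Wk, Wv, Wo, n_heads, d_k) {
  d <- dim(x)
  B <- d[1]; T_ <- d[2]; D <- d[3]
  xm <- matrix(x, B * T_, D)
  Q <- xm %*% Wq
  K <- xm %*% Wk
  V <- xm %*% Wv
  O <- matrix(0, B * T_, n_heads * d_k)
  A <- vector("list", B * n_heads)
  for (b in seq_len(B)) {
    rows <- seq(b, by = B, length.out = T_)   # (b, t) row index = b + (t-1)B
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * d_k + 1L):(h * d_k)
      Qh <- Q[rows, cols, drop = FALSE]
      Kh <- K[rows, cols, drop = FALSE]
      S <- (Qh %*% t(Kh)) / sqrt(d_k)
      Ah <- softmax_rows(S)
      O[rows, cols] <- Ah %*% V[rows, cols, drop = FALSE]
      A[[(b - 1L) * n_heads + h]] <- Ah
    }
  }
  y <- O %*% Wo
  list(y = array(y, c(B, T_, D)),
       cache = list(xm = xm, Q = Q, K = K, V = V, O = O, A = A,
                    Wq = Wq, Wk = Wk, Wv = Wv, Wo = Wo,
                    n_heads = n_heads, d_k = d_k, dims = d),
       weights = A)
}

attention_backward <- function(dy, cache) {
  d <- cache$dims
  B <- d[1]; T_ <- d[2]; D <- d[3]
  h <- cache$n_heads; d_k <- cache$d_k
  dym <- matrix(dy, B * T_, D)
  dWo <- t(cache$O) %*% dym
  dO <- dym %*% t(cache$Wo)
  dQ <- matrix(0, B * T_, h * d_k)
  dK <- matrix(0, B * T_, h * d_k)
  dV <- matrix(0, B * T_, h * d_k)
  for (b in seq_len(B)) {
    rows <- seq(b, by = B, length.out = T_)
    for (hh in seq_len(h)) {
      cols <- ((hh - 1L) * d_k + 1L):(hh * d_k)
      Ah <- cache$A[[(b - 1L) * h + hh]]
      dOh <- dO[rows, cols, drop = FALSE]
      Vh <- cache$V[rows, cols, drop = FALSE]
      dA <- dOh %*% t(Vh)
      dV[rows, cols] <- t(Ah) %*% dOh
      dS <- Ah * (dA - rowSums(dA * Ah))
      dQ[rows, cols] <- (dS %*% cache$K[rows, cols, drop = FALSE]) / sqrt(d_k)
      dK[rows, cols] <- (t(dS) %*% cache$Q[rows, cols, drop = FALSE]) / sqrt(d_k)
    }
  }
  dxm <- dQ %*% t(cache$Wq) + dK %*% t(cache$Wk) + dV %*% t(cache$Wv)
  list(dx = array(dxm, d),
       dWq = t(cache$xm) %*% dQ,
       dWk = t(cache$xm) %*% dK,
       dWv = t(cache$xm) %*% dV,
       dWo = dWo)
}

# ---- position-wise feed-forward ------------------------------------------

ffn_forward <- function(x, W1, b1, W2, b2) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  Z <- sweep(xm %*% W1, 2, b1, "+")
  A <- pmax(Z, 0)
  y <- sweep(A %*% W2, 2, b2, "+")
  list(y = array(y, d), cache = list(xm = xm, A = A, mask = Z > 0,
                                     W1 = W1, W2 = W2, dims = d))
}

ffn_backward <- function(dy, cache) {
  d <- cache$dims
  dym <- matrix(dy, d[1] * d[2], d[3])
  dW2 <- t(cache$A) %*% dym
  db2 <- colSums(dym)
  dA <- dym %*% t(cache$W2)
  dZ <- dA * cache$mask
  dW1 <- t(cache$xm) %*% dZ
  db1 <- colSums(dZ)
  dxm <- dZ %*% t(cache$W1)
  list(dx = array(dxm, d), dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# ---- inverted dropout -----------------------------------------------------

dropout_forward <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, cache = NULL))
  mask <- array(stats::runif(length(x)) >= rate, dim(x)) / (1 - rate)
  list(y = x * mask, cache = mask)
}

dropout_backward <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

# ---- LSTM (final hidden state) -------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

# x: B x T x D; Wx: D x 4H, Wh: H x 4H, b: 4H. Gate column order: i, f, o, g.
lstm_forward <- function(x, Wx, Wh, b) {
  d <- dim(x)
  B <- d[1]; T_ <- d[2]
  H <- ncol(Wh) %/% 4L
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  steps <- vector("list", T_)
  for (t in seq_len(T_)) {
    xt <- matrix(x[, t, ], B, d[3])
    Z <- sweep(xt %*% Wx + h %*% Wh, 2, b, "+")
    i_ <- sigmoid(Z[, 1:H, drop = FALSE])
    f_ <- sigmoid(Z[, (H + 1):(2 * H), drop = FALSE])
    o_ <- sigmoid(Z[, (2 * H + 1):(3 * H), drop = FALSE])
    g_ <- tanh(Z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f_ * cc + i_ * g_
    tc <- tanh(cc)
    h_prev <- h
    h <- o_ * tc
    steps[[t]] <- list(xt = xt, h_prev = h_prev, c_prev = c_prev,
                       i = i_, f = f_, o = o_, g = g_, c = cc, tc = tc)
  }
  list(y = h, cache = list(steps = steps, Wx = Wx, Wh = Wh, dims = d, H = H))
}

lstm_backward <- function(dh_final, cache) {
  d <- cache$dims
  B <- d[1]; T_ <- d[2]; D <- d[3]; H <- cache$H
  dWx <- matrix(0, D, 4 * H)
  dWh <- matrix(0, H, 4 * H)
  db <- numeric(4 * H)
  dx <- array(0, d)
  dh <- dh_final
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(T_))) {
    st <- cache$steps[[t]]
    do_ <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dc_prev <- dc * st$f
    dZ <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                do_ * st$o * (1 - st$o),
                dg * (1 - st$g^2))
    dWx <- dWx + t(st$xt) %*% dZ
    dWh <- dWh + t(st$h_prev) %*% dZ
    db <- db + colSums(dZ)
    dx[, t, ] <- dZ %*% t(cache$Wx)
    dh <- dZ %*% t(cache$Wh)
    dc <- dc_prev
  }
  list(dx = dx, dWx = dWx, dWh = dWh, db = db)
}

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}
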