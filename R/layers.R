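# Layer primitives: forward and backward passes for 1-D convolution (same
# padding, stride 1, im2col + BLAS matmul), valid max pooling with stride ==
# pool size, batch normalization, inverted dropout, time-axis concatenation,
# flatten, dense and (bi)directional LSTM. Activations (batch, length,
# channels) are stored as 3-D arrays in R's column-major order; "flat"
# activations are (batch, features) matrices.

.relu <- function(x) { x[x < 0] <- 0; x }

.as_mat <- function(a) {
  d <- dim(a)
  dim(a) <- c(d[1] * d[2], d[3])
  a
}

# ---- conv1d --------------------------------------------------------------

.conv1d_fwd <- function(X, W, b, kernel, activation) {
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  pl <- (kernel - 1L) %/% 2L; pr <- kernel - 1L - pl
  Xp <- array(0, c(B, L + pl + pr, C))
  Xp[, (pl + 1):(pl + L), ] <- X
  Z <- matrix(0, B * L, kernel * C)
  for (j in seq_len(kernel)) {
    blk <- Xp[, j:(j + L - 1), , drop = FALSE]
    dim(blk) <- c(B * L, C)
    Z[, ((j - 1) * C + 1):(j * C)] <- blk
  }
  A <- Z %*% W
  A <- sweep(A, 2, b, "+")
  mask <- if (activation == "relu") A > 0
  Y <- if (activation == "relu") .relu(A) else A
  out <- array(Y, c(B, L, ncol(W)))
  list(out = out, cache = list(Z = Z, mask = mask,
                               dims = d, kernel = kernel, pl = pl, pr = pr,
                               activation = activation))
}

.conv1d_bwd <- function(dY, cache, W) {
  d <- cache$dims; B <- d[1]; L <- d[2]; C <- d[3]
  Fo <- ncol(W)
  dA <- matrix(dY, B * L, Fo)
  if (cache$activation == "relu") dA <- dA * cache$mask
  dW <- crossprod(cache$Z, dA)
  db <- colSums(dA)
  dZ <- dA %*% t(W)
  dXp <- array(0, c(B, L + cache$pl + cache$pr, C))
  for (j in seq_len(cache$kernel)) {
    blk <- dZ[, ((j - 1) * C + 1):(j * C), drop = FALSE]
    dim(blk) <- c(B, L, C)
    dXp[, j:(j + L - 1), ] <- dXp[, j:(j + L - 1), , drop = FALSE] + blk
  }
  dX <- dXp[, (cache$pl + 1):(cache$pl + L), , drop = FALSE]
  list(dX = dX, grads = list(W = dW, b = db))
}

# ---- max pooling ---------------------------------------------------------

.maxpool_fwd <- function(X, pool) {
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  p <- min(pool, L)
  Lout <- L %/% p
  maxv <- array(-Inf, c(B, Lout, C))
  arg <- array(1L, c(B, Lout, C))
  for (i in seq_len(p)) {
    idx <- seq(i, by = p, length.out = Lout)
    s <- X[, idx, , drop = FALSE]
    dim(s) <- c(B, Lout, C)
    upd <- s > maxv
    maxv[upd] <- s[upd]
    arg[upd] <- i
  }
  list(out = maxv, cache = list(p = p, arg = arg, dims = d, Lout = Lout))
}

.maxpool_bwd <- function(dY, cache) {
  d <- cache$dims
  dX <- array(0, d)
  for (i in seq_len(cache$p)) {
    idx <- seq(i, by = cache$p, length.out = cache$Lout)
    dX[, idx, ] <- dY * (cache$arg == i)
  }
  dX
}

# ---- batch normalization -------------------------------------------------

.bn_fwd <- function(X, w, training, activation, momentum = 0.9,
                    eps = 1e-3) {
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  m <- .as_mat(X)
  if (training) {
    mu <- colMeans(m)
    va <- colMeans(m^2) - mu^2
    if (!isTRUE(w$initialized)) {
      # seed the moving statistics from the first batch: avoids a long
      # transient from the conventional (0, 1) start, which would make
      # inference-mode normalization disagree with training for many steps
      w$run_mean <- mu
      w$run_var <- va
      w$initialized <- TRUE
    } else {
      w$run_mean <- momentum * w$run_mean + (1 - momentum) * mu
      w$run_var <- momentum * w$run_var + (1 - momentum) * va
    }
  } else {
    mu <- w$run_mean; va <- w$run_var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(m, 2, mu, "-"), 2, invstd, "*")
  y <- sweep(sweep(xhat, 2, w$gamma, "*"), 2, w$beta, "+")
  if (activation == "relu") { mask <- y > 0; y <- .relu(y) } else mask <- NULL
  list(out = array(y, d), weights = w,
       cache = list(xhat = xhat, invstd = invstd, mask = mask, dims = d,
                    activation = activation, training = training))
}

.bn_bwd <- function(dY, cache, w) {
  d <- cache$dims
  N <- d[1] * d[2]
  dy <- matrix(dY, N, d[3])
  if (!is.null(cache$mask)) dy <- dy * cache$mask
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, w$gamma, "*")
  if (cache$training) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dx <- sweep(dxhat, 2, s1 / N, "-") -
      sweep(cache$xhat, 2, s2 / N, "*")
    dx <- sweep(dx, 2, cache$invstd, "*")
  } else {
    dx <- sweep(dxhat, 2, cache$invstd, "*")
  }
  list(dX = array(dx, d), grads = list(gamma = dgamma, beta = dbeta))
}

# ---- dropout -------------------------------------------------------------

.dropout_fwd <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, cache = NULL))
  mask <- array((stats::runif(length(X)) >= rate) / (1 - rate), dim(X))
  list(out = X * mask, cache = mask)
}

.dropout_bwd <- function(dY, cache) {
  if (is.null(cache)) dY else dY * cache
}

# ---- dense ---------------------------------------------------------------

.dense_fwd <- function(X, W, b, activation) {
  A <- X %*% W
  A <- sweep(A, 2, b, "+")
  Y <- switch(activation,
              relu = .relu(A),
              softmax = {
                e <- exp(A - apply(A, 1, max))
                e / rowSums(e)
              },
              A)
  list(out = Y, cache = list(X = X, mask = if (activation == "relu") Y > 0,
                             activation = activation))
}

# For softmax the incoming dY must already be the gradient w.r.t. the
# pre-activation (the trainer folds softmax + cross-entropy together).
.dense_bwd <- function(dY, cache, W) {
  dA <- if (cache$activation == "relu") dY * cache$mask else dY
  list(dX = dA %*% t(W),
       grads = list(W = crossprod(cache$X, dA), b = colSums(dA)))
}

# ---- LSTM ----------------------------------------------------------------
# Gate order [i, f, c~, o]; returns the final hidden state. Short sequences
# only (the recurrent variants sit after the last pooling stage).

.sigmoid <- function(x) 1 / (1 + exp(-x))

.lstm_fwd_dir <- function(X, w, reverse = FALSE) {
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  U <- ncol(w$Wh) %/% 4L
  order_t <- if (reverse) rev(seq_len(L)) else seq_len(L)
  h <- matrix(0, B, U); cst <- matrix(0, B, U)
  steps <- vector("list", L)
  for (s in seq_len(L)) {
    t <- order_t[s]
    xt <- X[, t, , drop = FALSE]; dim(xt) <- c(B, C)
    g <- xt %*% w$Wx + h %*% w$Wh
    g <- sweep(g, 2, w$b, "+")
    i_g <- .sigmoid(g[, 1:U, drop = FALSE])
    f_g <- .sigmoid(g[, (U + 1):(2 * U), drop = FALSE])
    c_g <- tanh(g[, (2 * U + 1):(3 * U), drop = FALSE])
    o_g <- .sigmoid(g[, (3 * U + 1):(4 * U), drop = FALSE])
    c_new <- f_g * cst + i_g * c_g
    tc <- tanh(c_new)
    steps[[s]] <- list(xt = xt, h_prev = h, c_prev = cst, i = i_g, f = f_g,
                       cg = c_g, o = o_g, tc = tc, t = t)
    cst <- c_new
    h <- o_g * tc
  }
  list(out = h, cache = list(steps = steps, dims = d, U = U))
}

.lstm_bwd_dir <- function(dH, cache, w) {
  d <- cache$dims; B <- d[1]; L <- d[2]; C <- d[3]; U <- cache$U
  dWx <- matrix(0, C, 4 * U); dWh <- matrix(0, U, 4 * U); db <- numeric(4 * U)
  dX <- array(0, d)
  dc <- matrix(0, B, U)
  for (s in rev(seq_len(L))) {
    st <- cache$steps[[s]]
    do_g <- dH * st$tc * st$o * (1 - st$o)
    dc <- dc + dH * st$o * (1 - st$tc^2)
    di <- dc * st$cg * st$i * (1 - st$i)
    df <- dc * st$c_prev * st$f * (1 - st$f)
    dcg <- dc * st$i * (1 - st$cg^2)
    dg <- cbind(di, df, dcg, do_g)
    dWx <- dWx + crossprod(st$xt, dg)
    dWh <- dWh + crossprod(st$h_prev, dg)
    db <- db + colSums(dg)
    dX[, st$t, ] <- dg %*% t(w$Wx)
    dH <- dg %*% t(w$Wh)
    dc <- dc * st$f
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
}
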