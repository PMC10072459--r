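# Network instantiation and DAG execution. A "network" pairs a plan with a
# list of weight tensors (one entry per layer index); forward and backward
# passes walk the plan, which is topologically ordered by construction.

.glorot <- function(fan_in, fan_out, nr, nc) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

.layer_in_ch <- function(plan, i) {
  l <- plan$layers[[i]]
  up <- plan$layers[[l$inputs[1]]]
  up$out_ch
}

#' Instantiate a network from a plan
#'
#' Allocates weight tensors for every parametric layer: Glorot-uniform
#' kernels, zero biases (LSTM forget-gate bias 1), unit batch-norm scale.
#' Uses the current RNG state; seed externally for reproducible
#' initialization.
#'
#' @param plan A `network_plan` from [build_compressor_plan()] or
#'   [build_classifier_plan()].
#' @return A `network` object (plan + weights).
#' @export
init_network <- function(plan) {
  stopifnot(inherits(plan, "network_plan"))
  weights <- vector("list", length(plan$layers))
  for (i in seq_along(plan$layers)) {
    l <- plan$layers[[i]]
    weights[[i]] <- switch(
      l$kind,
      conv1d = {
        cin <- .layer_in_ch(plan, i)
        list(W = .glorot(l$kernel * cin, l$kernel * l$filters,
                         l$kernel * cin, l$filters),
             b = numeric(l$filters))
      },
      dense = {
        fin <- plan$layers[[l$inputs[1]]]$out_len
        list(W = .glorot(fin, l$units, fin, l$units), b = numeric(l$units))
      },
      batchnorm = {
        ch <- l$out_ch
        list(gamma = rep(1, ch), beta = numeric(ch),
             run_mean = numeric(ch), run_var = rep(1, ch),
             initialized = FALSE)
      },
      lstm = ,
      bilstm = {
        cin <- .layer_in_ch(plan, i)
        u <- l$units
        mk <- function() {
          b <- numeric(4 * u); b[(u + 1):(2 * u)] <- 1
          list(Wx = .glorot(cin + u, u, cin, 4 * u),
               Wh = .glorot(cin + u, u, u, 4 * u), b = b)
        }
        if (l$kind == "bilstm") list(fwd = mk(), bwd = mk()) else mk()
      },
      NULL)
  }
  structure(list(plan = plan, weights = weights), class = "cdecg_network")
}

#' Count trainable parameters of an instantiated network
#'
#' Brute-force count over the allocated weight tensors (batch-norm moving
#' statistics excluded); agrees with the plan's `trainable_params`.
#'
#' @param network A `cdecg_network`.
#' @return Integer parameter count.
#' @export
count_network_params <- function(network) {
  stopifnot(inherits(network, "cdecg_network"))
  total <- 0L
  for (i in seq_along(network$weights)) {
    w <- network$weights[[i]]
    if (is.null(w)) next
    kind <- network$plan$layers[[i]]$kind
    tensors <- if (kind == "batchnorm") w[c("gamma", "beta")]
               else if (kind == "bilstm") c(w$fwd, w$bwd)
               else w
    total <- total + sum(vapply(tensors, length, integer(1)))
  }
  as.integer(total)
}

# Forward pass. X: (batch x input_len) matrix. Returns the final output and
# per-layer caches for backprop; `training` switches batch-norm statistics
# and dropout sampling.
.net_forward <- function(network, X, training = FALSE) {
  plan <- network$plan
  nl <- length(plan$layers)
  outs <- vector("list", nl)
  caches <- vector("list", nl)
  for (i in seq_len(nl)) {
    l <- plan$layers[[i]]
    if (l$kind == "input") {
      if (ncol(X) != l$out_len)
        stop("input has ", ncol(X), " samples per row, network expects ",
             l$out_len)
      outs[[i]] <- array(as.numeric(X), c(nrow(X), l$out_len, 1L))
      next
    }
    up <- outs[[l$inputs[1]]]
    w <- network$weights[[i]]
    res <- switch(
      l$kind,
      conv1d = .conv1d_fwd(up, w$W, w$b, l$kernel, l$activation),
      maxpool1d = .maxpool_fwd(up, l$pool),
      batchnorm = {
        r <- .bn_fwd(up, w, training, l$activation)
        if (training) network$weights[[i]] <- r$weights
        r
      },
      dropout = .dropout_fwd(up, l$rate, training),
      concatenate = {
        up2 <- outs[[l$inputs[2]]]
        d1 <- dim(up); d2 <- dim(up2)
        out <- array(0, c(d1[1], d1[2] + d2[2], d1[3]))
        out[, seq_len(d1[2]), ] <- up
        out[, d1[2] + seq_len(d2[2]), ] <- up2
        list(out = out, cache = list(split = d1[2]))
      },
      flatten = {
        d <- dim(up)
        list(out = matrix(up, d[1], d[2] * d[3]), cache = list(dims = d))
      },
      dense = .dense_fwd(up, w$W, w$b, l$activation),
      lstm = .lstm_fwd_dir(up, w, reverse = FALSE),
      bilstm = {
        f <- .lstm_fwd_dir(up, w$fwd, reverse = FALSE)
        b <- .lstm_fwd_dir(up, w$bwd, reverse = TRUE)
        list(out = cbind(f$out, b$out),
             cache = list(f = f$cache, b = b$cache, units = l$units))
      },
      stop("no forward rule for layer kind ", l$kind))
    outs[[i]] <- res$out
    caches[[i]] <- res$cache
  }
  list(out = outs[[nl]], outs = outs, caches = caches, network = network)
}

# Backward pass. dOut is the gradient at the final layer's output (for a
# softmax head: at the pre-activation). Returns per-layer gradients and the
# gradient at the network input as a (batch x input_len) matrix.
.net_backward <- function(fwd, dOut) {
  network <- fwd$network
  plan <- network$plan
  nl <- length(plan$layers)
  grads <- vector("list", nl)
  pend <- vector("list", nl)
  pend[[nl]] <- dOut
  acc <- function(i, d) {
    pend[[i]] <<- if (is.null(pend[[i]])) d else pend[[i]] + d
  }
  for (i in rev(seq_len(nl))) {
    l <- plan$layers[[i]]
    if (l$kind == "input") next
    dY <- pend[[i]]
    if (is.null(dY)) next
    w <- network$weights[[i]]
    cache <- fwd$caches[[i]]
    switch(
      l$kind,
      conv1d = {
        r <- .conv1d_bwd(dY, cache, w$W)
        grads[[i]] <- r$grads
        acc(l$inputs[1], r$dX)
      },
      maxpool1d = acc(l$inputs[1], .maxpool_bwd(dY, cache)),
      batchnorm = {
        r <- .bn_bwd(dY, cache, w)
        grads[[i]] <- r$grads
        acc(l$inputs[1], r$dX)
      },
      dropout = acc(l$inputs[1], .dropout_bwd(dY, cache)),
      concatenate = {
        s <- cache$split
        d <- dim(dY)
        acc(l$inputs[1], dY[, seq_len(s), , drop = FALSE])
        acc(l$inputs[2], dY[, (s + 1):d[2], , drop = FALSE])
      },
      flatten = acc(l$inputs[1], array(dY, cache$dims)),
      dense = {
        r <- .dense_bwd(dY, cache, w$W)
        grads[[i]] <- r$grads
        acc(l$inputs[1], r$dX)
      },
      lstm = {
        r <- .lstm_bwd_dir(dY, cache, w)
        grads[[i]] <- r$grads
        acc(l$inputs[1], r$dX)
      },
      bilstm = {
        u <- cache$units
        rf <- .lstm_bwd_dir(dY[, seq_len(u), drop = FALSE], cache$f, w$fwd)
        rb <- .lstm_bwd_dir(dY[, u + seq_len(u), drop = FALSE], cache$b,
                            w$bwd)
        grads[[i]] <- list(fwd = rf$grads, bwd = rb$grads)
        acc(l$inputs[1], rf$dX + rb$dX)
      },
      stop("no backward rule for layer kind ", l$kind))
  }
  dIn <- pend[[1]]
  if (!is.null(dIn) && length(dim(dIn)) == 3) {
    d <- dim(dIn)
    dIn <- matrix(dIn, d[1], d[2])
  }
  list(grads = grads, dInput = dIn)
}

#' Run a compressor network in inference mode
#'
#' @param model A `cdecg_network` built from a compressor plan, or a
#'   [train_model()] result (its compressor is used).
#' @param beats A [beat_dataset()] or numeric matrix whose row length
#'   matches the network input.
#' @return Numeric matrix (n_beats x k) of compressed representations.
#' @export
compress_forward <- function(model, beats) {
  if (inherits(model, "cdecg_model")) model <- model$compressor
  stopifnot(inherits(model, "cdecg_network"))
  X <- if (inherits(beats, "beat_dataset")) beats$beats else as.matrix(beats)
  .net_forward(model, X, training = FALSE)$out
}

#' Run a classifier network in inference mode
#'
#' Dropout is disabled and batch normalization uses its running statistics,
#' so outputs are deterministic. Each output row is a probability vector
#' (non-negative, summing to 1).
#'
#' @param model A `cdecg_network` built from a classifier plan, or a
#'   [train_model()] result (its classifier is used).
#' @param compressed Numeric matrix (n_beats x k).
#' @return Matrix (n_beats x n_classes) of class probabilities.
#' @export
classify_forward <- function(model, compressed) {
  if (inherits(model, "cdecg_model")) model <- model$classifier
  stopifnot(inherits(model, "cdecg_network"))
  .net_forward(model, as.matrix(compressed), training = FALSE)$out
}
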