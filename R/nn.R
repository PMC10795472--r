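# Minimal neural-network engine: batched LSTM and MLP layers with manual
# backpropagation and an Adam optimizer. Kept deliberately small: the only
# architectures it needs to support are the event classifier (LSTM readout +
# ReLU MLP + softmax) and the assessment network (LSTM + tanh MLP + sigmoid).
# All tensors are base-R matrices/arrays; matrix products go through BLAS.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Glorot-uniform initialization
glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

nn_init_lstm <- function(input_size, state_size) {
  b <- numeric(4 * state_size)
  # forget-gate bias at 1: standard remedy for early gradient vanishing
  b[(state_size + 1):(2 * state_size)] <- 1
  list(Wx = glorot(input_size, 4 * state_size),
       Wh = glorot(state_size, 4 * state_size),
       b  = b,
       H  = state_size)
}

nn_init_mlp <- function(input_size, hidden, output_size) {
  sizes <- c(input_size, hidden, output_size)
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    layers[[l]] <- list(W = glorot(sizes[l], sizes[l + 1L]),
                        b = numeric(sizes[l + 1L]))
  }
  layers
}

# X: (B, T, D) array; mask: (B, T) 0/1 matrix. Steps where mask = 0 carry the
# previous state through unchanged, so the state after step T is the state at
# each sequence's last valid element (padding-invariant readout).
nn_lstm_forward <- function(p, X, mask, cache = FALSE) {
  B <- dim(X)[1]; Tn <- dim(X)[2]; H <- p$H
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  steps <- if (cache) vector("list", Tn) else NULL
  idx_i <- 1:H; idx_f <- H + 1:H; idx_o <- 2 * H + 1:H; idx_g <- 3 * H + 1:H
  for (t in seq_len(Tn)) {
    x <- X[, t, , drop = FALSE]; dim(x) <- c(B, dim(X)[3])
    z <- x %*% p$Wx + h %*% p$Wh
    z <- sweep(z, 2, p$b, "+")
    gi <- sigmoid(z[, idx_i, drop = FALSE])
    gf <- sigmoid(z[, idx_f, drop = FALSE])
    go <- sigmoid(z[, idx_o, drop = FALSE])
    gg <- tanh(z[, idx_g, drop = FALSE])
    c_new <- gf * cc + gi * gg
    tc <- tanh(c_new)
    h_new <- go * tc
    m <- mask[, t]
    if (cache) {
      steps[[t]] <- list(x = x, h_prev = h, c_prev = cc,
                         gi = gi, gf = gf, go = go, gg = gg, tc = tc, m = m)
    }
    h <- m * h_new + (1 - m) * h
    cc <- m * c_new + (1 - m) * cc
  }
  list(h = h, steps = steps)
}

nn_lstm_backward <- function(p, fwd, dh_final) {
  steps <- fwd$steps
  H <- p$H
  dWx <- array(0, dim(p$Wx)); dWh <- array(0, dim(p$Wh)); db <- numeric(length(p$b))
  dh <- dh_final; dc <- array(0, dim(dh_final))
  for (t in rev(seq_along(steps))) {
    s <- steps[[t]]; m <- s$m
    dh_new <- m * dh; dh_carry <- (1 - m) * dh
    dc_new <- m * dc; dc_carry <- (1 - m) * dc
    dgo <- dh_new * s$tc
    dc_new <- dc_new + dh_new * s$go * (1 - s$tc^2)
    dgf <- dc_new * s$c_prev
    dgi <- dc_new * s$gg
    dgg <- dc_new * s$gi
    dc_prev <- dc_new * s$gf
    dz <- cbind(dgi * s$gi * (1 - s$gi),
                dgf * s$gf * (1 - s$gf),
                dgo * s$go * (1 - s$go),
                dgg * (1 - s$gg^2))
    dWx <- dWx + crossprod(s$x, dz)
    dWh <- dWh + crossprod(s$h_prev, dz)
    db <- db + colSums(dz)
    dh <- dh_carry + dz %*% t(p$Wh)
    dc <- dc_carry + dc_prev
  }
  list(Wx = dWx, Wh = dWh, b = db)
}

nn_mlp_forward <- function(layers, X, act = c("relu", "tanh"), cache = FALSE) {
  act <- match.arg(act)
  nl <- length(layers)
  caches <- if (cache) vector("list", nl) else NULL
  a <- X
  for (l in seq_len(nl)) {
    z <- sweep(a %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    if (l < nl) {
      out <- if (act == "relu") pmax(z, 0) else tanh(z)
    } else {
      out <- z  # output layer linear; softmax/sigmoid applied by the loss
    }
    if (cache) caches[[l]] <- list(a_in = a, z = z)
    a <- out
  }
  list(out = a, caches = caches)
}

# dOut = gradient wrt the (linear) output; returns per-layer grads and the
# gradient wrt the MLP input (to chain into the LSTM state).
nn_mlp_backward <- function(layers, fwd, dOut, act = c("relu", "tanh")) {
  act <- match.arg(act)
  nl <- length(layers)
  grads <- vector("list", nl)
  d <- dOut
  for (l in rev(seq_len(nl))) {
    cc <- fwd$caches[[l]]
    if (l < nl) {
      d <- if (act == "relu") d * (cc$z > 0) else d * (1 - tanh(cc$z)^2)
    }
    grads[[l]] <- list(W = crossprod(cc$a_in, d), b = colSums(d))
    d <- d %*% t(layers[[l]]$W)
  }
  list(grads = grads, dX = d)
}

# --- flat parameter plumbing for the optimizer ------------------------------

nn_flatten <- function(net) {
  out <- list(net$lstm$Wx, net$lstm$Wh, net$lstm$b)
  for (l in net$mlp) out <- c(out, list(l$W, l$b))
  out
}

nn_unflatten <- function(net, flat) {
  net$lstm$Wx <- flat[[1]]; net$lstm$Wh <- flat[[2]]; net$lstm$b <- flat[[3]]
  k <- 4L
  for (l in seq_along(net$mlp)) {
    net$mlp[[l]]$W <- flat[[k]]; net$mlp[[l]]$b <- flat[[k + 1L]]
    k <- k + 2L
  }
  net
}

nn_grads_flatten <- function(lstm_g, mlp_g) {
  out <- list(lstm_g$Wx, lstm_g$Wh, lstm_g$b)
  for (l in mlp_g) out <- c(out, list(l$W, l$b))
  out
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(flat, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(state, flat, grads, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in seq_along(flat)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    flat[[k]] <- flat[[k]] - lr * (state$m[[k]] / bc1) /
      (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(state = state, flat = flat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Numerically stable row-wise softmax
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# One full network (LSTM reader + MLP head) forward pass on a padded batch.
nn_net_forward <- function(net, X, mask, cache = FALSE) {
  lf <- nn_lstm_forward(net$lstm, X, mask, cache = cache)
  mf <- nn_mlp_forward(net$mlp, lf$h, act = net$act, cache = cache)
  list(out = mf$out, lstm_fwd = lf, mlp_fwd = mf)
}

nn_net_backward <- function(net, fwd, dOut) {
  mb <- nn_mlp_backward(net$mlp, fwd$mlp_fwd, dOut, act = net$act)
  lb <- nn_lstm_backward(net$lstm, fwd$lstm_fwd, mb$dX)
  nn_grads_flatten(lb, mb$grads)
}
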