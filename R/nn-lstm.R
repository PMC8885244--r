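# Long short-term memory cells with exact backpropagation through time.
# A cell fuses its four gates into one weight matrix W of shape
# (4h) x (d_in + h): rows 1..h input gate (sigmoid), h+1..2h forget gate
# (sigmoid, bias initialised at +1), 2h+1..3h candidate (tanh),
# 3h+1..4h output gate (sigmoid).

lstm_cell_init <- function(d_in, h) {
  W <- rand_mat(4 * h, d_in + h, scale = 1 / sqrt(d_in + h))
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1        # forget-gate bias: remember by default
  list(W = W, b = b)
}

## Forward over a whole sequence.  X: M x d_in.  Returns H (M x h) and a
## cache of per-step gate activations for the backward pass.
lstm_forward <- function(X, p) {
  m <- nrow(X)
  h <- length(p$b) / 4L
  H <- matrix(0, m, h)
  Cs <- matrix(0, m, h)
  gates <- vector("list", m)
  hprev <- numeric(h)
  cprev <- numeric(h)
  for (t in seq_len(m)) {
    z <- as.numeric(p$W %*% c(X[t, ], hprev)) + p$b
    ig <- sigmoid(z[1:h])
    fg <- sigmoid(z[(h + 1):(2 * h)])
    gg <- tanh(z[(2 * h + 1):(3 * h)])
    og <- sigmoid(z[(3 * h + 1):(4 * h)])
    c_t <- fg * cprev + ig * gg
    tc <- tanh(c_t)
    h_t <- og * tc
    H[t, ] <- h_t
    Cs[t, ] <- c_t
    gates[[t]] <- list(i = ig, f = fg, g = gg, o = og, tc = tc, cprev = cprev)
    hprev <- h_t
    cprev <- c_t
  }
  list(H = H, cache = list(X = X, H = H, Cs = Cs, gates = gates))
}

## Backward: dH is M x h gradient w.r.t. the hidden outputs.
lstm_backward <- function(dH, p, cache) {
  X <- cache$X
  m <- nrow(X)
  h <- ncol(dH)
  dW <- p$W * 0
  db <- p$b * 0
  dX <- X * 0
  dh_next <- numeric(h)
  dc_next <- numeric(h)
  for (t in rev(seq_len(m))) {
    g <- cache$gates[[t]]
    dh <- dH[t, ] + dh_next
    do_ <- dh * g$tc
    dc <- dc_next + dh * g$o * (1 - g$tc^2)
    di <- dc * g$g
    dg <- dc * g$i
    df <- dc * g$cprev
    dc_next <- dc * g$f
    dz <- c(di * g$i * (1 - g$i),
            df * g$f * (1 - g$f),
            dg * (1 - g$g^2),
            do_ * g$o * (1 - g$o))
    hprev <- if (t > 1) cache$H[t - 1, ] else numeric(h)
    xh <- c(X[t, ], hprev)
    dW <- dW + outer(dz, xh)
    db <- db + dz
    dxh <- as.numeric(t(p$W) %*% dz)
    dX[t, ] <- dxh[seq_len(ncol(X))]
    dh_next <- dxh[(ncol(X) + 1):(ncol(X) + h)]
  }
  list(dX = dX, grads = list(W = dW, b = db))
}

## A bidirectional layer: forward cell over the sequence, backward cell
## over the reversed sequence, hidden states concatenated (M x 2h).
bilstm_layer_init <- function(d_in, h) {
  list(fwd = lstm_cell_init(d_in, h), bwd = lstm_cell_init(d_in, h))
}

bilstm_layer_forward <- function(X, p) {
  f <- lstm_forward(X, p$fwd)
  b <- lstm_forward(X[rev(seq_len(nrow(X))), , drop = FALSE], p$bwd)
  Hb <- b$H[rev(seq_len(nrow(X))), , drop = FALSE]
  list(H = cbind(f$H, Hb), cache = list(f = f$cache, b = b$cache))
}

bilstm_layer_backward <- function(dH, p, cache) {
  h <- ncol(dH) / 2L
  m <- nrow(dH)
  gf <- lstm_backward(dH[, seq_len(h), drop = FALSE], p$fwd, cache$f)
  gb <- lstm_backward(dH[rev(seq_len(m)), (h + 1):(2 * h), drop = FALSE], p$bwd, cache$b)
  list(dX = gf$dX + gb$dX[rev(seq_len(m)), , drop = FALSE],
       grads = list(fwd = gf$grads, bwd = gb$grads))
}

bilstm_stack_init <- function(d_in, h, layers) {
  out <- vector("list", layers)
  din <- d_in
  for (l in seq_len(layers)) {
    out[[l]] <- bilstm_layer_init(din, h)
    din <- 2 * h
  }
  out
}

bilstm_stack_forward <- function(X, params) {
  caches <- vector("list", length(params))
  H <- X
  for (l in seq_along(params)) {
    r <- bilstm_layer_forward(H, params[[l]])
    H <- r$H
    caches[[l]] <- r$cache
  }
  list(H = H, caches = caches)
}

bilstm_stack_backward <- function(dH, params, caches) {
  grads <- vector("list", length(params))
  for (l in rev(seq_along(params))) {
    r <- bilstm_layer_backward(dH, params[[l]], caches[[l]])
    dH <- r$dX
    grads[[l]] <- r$grads
  }
  list(dX = dH, grads = grads)
}
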