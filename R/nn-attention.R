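# Encoder blocks for the toy contextual encoder: a local convolutional
# sublayer (window +/-2, tanh, residual) captures neighbourhood patterns
# such as "entity character next to a connector word", a single-head
# self-attention sublayer (residual) mixes global sentence context, and
# a position-wise feed-forward sublayer (tanh, residual) adds capacity:
#   Xc = X  + tanh(sum_{k=-2..2} shift(X, k) Wk + bc)
#   Xa = Xc + softmax(Xc Wq (Xc Wk)^T / sqrt(d)) (Xc Wv)
#   Xo = Xa + tanh(Xa Wf1 + bf1) Wf2
# Forward caches every intermediate needed for the analytic backward
# pass; gradients are verified against finite differences in the tests.

## rows shifted by k: row i of the result is row i-k of X (zero-padded)
shift_rows <- function(X, k) {
  m <- nrow(X)
  out <- X * 0
  if (k >= 0) {
    if (m > k) out[(k + 1):m, ] <- X[seq_len(m - k), , drop = FALSE]
  } else {
    if (m > -k) out[seq_len(m + k), ] <- X[(1 - k):m, , drop = FALSE]
  }
  out
}

attn_layer_init <- function(d, ff) {
  conv <- lapply(1:5, function(i) rand_mat(d, d, scale = 0.5 / sqrt(d)))
  names(conv) <- c("W0", "Wm1", "Wp1", "Wm2", "Wp2")
  c(conv,
    list(bc = numeric(d),
         Wq = rand_mat(d, d), Wk = rand_mat(d, d), Wv = rand_mat(d, d),
         Wf1 = rand_mat(d, ff), bf1 = numeric(ff),
         Wf2 = rand_mat(ff, d, scale = 0.5 / sqrt(ff))))
}

conv_offsets <- c(W0 = 0L, Wm1 = 1L, Wp1 = -1L, Wm2 = 2L, Wp2 = -2L)

attn_layer_forward <- function(X, p) {
  d <- ncol(X)
  ## convolutional sublayer
  Cpre <- matrix(p$bc, nrow(X), d, byrow = TRUE)
  for (nm in names(conv_offsets)) {
    Cpre <- Cpre + shift_rows(X, conv_offsets[[nm]]) %*% p[[nm]]
  }
  Ch <- tanh(Cpre)
  Xc <- X + Ch
  ## attention sublayer
  Q <- Xc %*% p$Wq
  K <- Xc %*% p$Wk
  V <- Xc %*% p$Wv
  S <- Q %*% t(K) / sqrt(d)
  S <- S - apply(S, 1, max)              # row-wise stabilisation
  A <- exp(S)
  A <- A / rowSums(A)
  Xa <- Xc + A %*% V
  ## feed-forward sublayer
  Fpre <- sweep(Xa %*% p$Wf1, 2, p$bf1, `+`)
  Fh <- tanh(Fpre)
  Xo <- Xa + Fh %*% p$Wf2
  list(out = Xo, cache = list(X = X, Ch = Ch, Xc = Xc, Q = Q, K = K, V = V,
                              A = A, Xa = Xa, Fh = Fh))
}

attn_layer_backward <- function(dXo, p, cache) {
  d <- ncol(cache$X)
  ## feed-forward half
  dFh <- dXo %*% t(p$Wf2)
  dWf2 <- t(cache$Fh) %*% dXo
  dFpre <- dFh * (1 - cache$Fh^2)
  dWf1 <- t(cache$Xa) %*% dFpre
  dbf1 <- colSums(dFpre)
  dXa <- dXo + dFpre %*% t(p$Wf1)
  ## attention half
  dAV <- dXa
  dA <- dAV %*% t(cache$V)
  dV <- t(cache$A) %*% dAV
  dS <- cache$A * (dA - rowSums(dA * cache$A))
  dQ <- dS %*% cache$K / sqrt(d)
  dK <- t(dS) %*% cache$Q / sqrt(d)
  dXc <- dXa +
    dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  ## convolutional half
  dCpre <- dXc * (1 - cache$Ch^2)
  dX <- dXc
  grads <- list()
  for (nm in names(conv_offsets)) {
    k <- conv_offsets[[nm]]
    grads[[nm]] <- t(shift_rows(cache$X, k)) %*% dCpre
    dX <- dX + shift_rows(dCpre %*% t(p[[nm]]), -k)
  }
  grads$bc <- colSums(dCpre)
  grads$Wq <- t(cache$Xc) %*% dQ
  grads$Wk <- t(cache$Xc) %*% dK
  grads$Wv <- t(cache$Xc) %*% dV
  grads$Wf1 <- dWf1
  grads$bf1 <- dbf1
  grads$Wf2 <- dWf2
  ## order must match attn_layer_init for tree arithmetic
  grads <- grads[c(names(conv_offsets), "bc", "Wq", "Wk", "Wv", "Wf1", "bf1", "Wf2")]
  list(dX = dX, grads = grads)
}
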