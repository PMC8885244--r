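# Minimal neural-network plumbing: parameter trees (nested lists of
# numeric matrices/vectors), elementwise tree arithmetic, and Adam.
# All components in this package are small enough that plain R matrix
# algebra on a CPU is adequate; gradients are derived analytically and
# verified against finite differences in the test suite.

rand_mat <- function(nrow, ncol, scale = NULL) {
  scale <- scale %||% (1 / sqrt(ncol))
  matrix(stats::rnorm(nrow * ncol, sd = scale), nrow = nrow, ncol = ncol)
}

zeros_like <- function(p) {
  if (is.list(p)) return(lapply(p, zeros_like))
  p * 0
}

tree_add <- function(a, b) {
  if (is.list(a)) return(mapply(tree_add, a, b, SIMPLIFY = FALSE))
  a + b
}

tree_scale <- function(a, k) {
  if (is.list(a)) return(lapply(a, tree_scale, k = k))
  a * k
}

tree_apply2 <- function(a, b, f) {
  if (is.list(a)) return(mapply(tree_apply2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE))
  f(a, b)
}

## Flatten a parameter tree into a single numeric vector (for finite
## difference checks) and write a vector back into the tree shape.
tree_flatten <- function(p) {
  if (is.list(p)) return(unlist(lapply(p, tree_flatten), use.names = FALSE))
  as.numeric(p)
}

tree_unflatten <- function(p, v) {
  pos <- 0L
  rebuild <- function(x) {
    if (is.list(x)) return(lapply(x, rebuild))
    n <- length(x)
    out <- x
    out[] <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    out
  }
  rebuild(p)
}

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

## One Adam update; returns list(params, state).
adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_apply2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_apply2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_apply2(state$m, state$v, function(m, v) {
    lr * (m / bc1) / (sqrt(v / bc2) + eps)
  })
  params <- tree_apply2(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

## Mean binary cross-entropy of probabilities p against 0/1 labels y.
bce_loss <- function(p, y) {
  p <- clip_prob(p)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

## Sinusoidal position encoding, rows 1..m, width d.
position_encoding <- function(m, d) {
  pos <- matrix(0, m, d)
  i <- seq_len(ceiling(d / 2)) - 1L
  freq <- 1 / (10000^(2 * i / d))
  t <- seq_len(m) - 1L
  ang <- outer(t, freq)
  pos[, 2 * i + 1L] <- sin(ang)
  cols <- 2 * i + 2L
  keep <- cols <= d
  pos[, cols[keep]] <- cos(ang)[, keep, drop = FALSE]
  pos
}
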