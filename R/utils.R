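# Internal numeric and RNG helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## probabilities clipped away from {0,1} before taking logs
clip_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

## Deterministically derive a sub-seed from a base seed and a stream index.
## Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  ((as.numeric(seed) %% 2147483647) * 48271 + as.numeric(stream) * 9973 + 1) %%
    2147483647
}

## split a string into single characters
chars_of <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (nchar(text) == 0L) character(0) else strsplit(text, "", fixed = TRUE)[[1L]]
}

stop_bad <- function(...) stop(sprintf(...), call. = FALSE)
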