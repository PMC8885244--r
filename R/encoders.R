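#' Build a token vocabulary
#'
#' @param tokens character vector of observed tokens.
#' @return named integer vector mapping token to index; index 1 is the
#'   reserved `<UNK>` token covering anything unseen.
#' @export
make_vocab <- function(tokens) {
  toks <- unique(tokens)
  v <- seq_len(length(toks) + 1L)
  names(v) <- c("<UNK>", toks)
  v
}

tokens_to_ids <- function(tokens, vocab) {
  ids <- unname(vocab[tokens])
  ids[is.na(ids)] <- 1L
  as.integer(ids)
}

#' Configure a contextual encoder
#'
#' The default `"toy"` backend is a small trainable transformer: token
#' embeddings plus sinusoidal position encodings, followed by `layers`
#' single-head self-attention blocks with residual feed-forward sublayers.
#' With `layers = 0` the encoder degenerates to position-aware embeddings
#' (useful when a recurrent layer downstream supplies the context).
#' Character, radical, and word encoders share this architecture but
#' never share weights: each granularity gets its own vocabulary and its
#' own parameter set.  All initialisation randomness flows from `seed`.
#'
#' @param vocab named integer vector from [make_vocab()].
#' @param dim embedding width `d` (>= 2; default 32).
#' @param layers number of attention blocks (default 2).
#' @param ff_dim feed-forward width (default `dim`).
#' @param seed integer seed for weight initialisation.
#' @param backend `"toy"` is the only bundled backend; the argument is the
#'   hook for plugging in a pretrained encoder adapter.
#' @return an `encoder_config` list.
#' @export
encoder_config <- function(vocab, dim = 32L, layers = 2L, ff_dim = dim,
                           seed = 1L, backend = "toy") {
  stopifnot(dim >= 2, layers >= 0)
  if (backend != "toy") stop_bad("unknown encoder backend '%s'", backend)
  structure(list(vocab = vocab, dim = as.integer(dim),
                 layers = as.integer(layers), ff_dim = as.integer(ff_dim),
                 seed = as.integer(seed), backend = backend),
            class = "encoder_config")
}

#' Instantiate a toy encoder from a configuration
#'
#' Deterministic given `cfg$seed`: the same configuration always yields
#' identical weights.
#'
#' @param cfg an [encoder_config()].
#' @return a `toy_encoder` holding the configuration and parameter tree.
#' @export
build_encoder <- function(cfg) {
  stopifnot(inherits(cfg, "encoder_config"))
  params <- with_seed(cfg$seed, {
    list(emb = rand_mat(length(cfg$vocab), cfg$dim),
         blocks = lapply(seq_len(cfg$layers), function(i) {
           attn_layer_init(cfg$dim, cfg$ff_dim)
         }))
  })
  structure(list(cfg = cfg, params = params), class = "toy_encoder")
}

## Forward pass over token ids; cache everything when training.
encoder_forward <- function(enc, ids, cache = FALSE) {
  stopifnot(length(ids) >= 1)
  X <- enc$params$emb[ids, , drop = FALSE] +
    position_encoding(length(ids), enc$cfg$dim)
  caches <- if (cache) vector("list", length(enc$params$blocks)) else NULL
  for (l in seq_along(enc$params$blocks)) {
    r <- attn_layer_forward(X, enc$params$blocks[[l]])
    X <- r$out
    if (cache) caches[[l]] <- r$cache
  }
  list(H = X, ids = ids, caches = caches)
}

## Backward: dH (M x d) -> gradient tree matching enc$params.
encoder_backward <- function(enc, fwd, dH) {
  grads_blocks <- vector("list", length(enc$params$blocks))
  dX <- dH
  for (l in rev(seq_along(enc$params$blocks))) {
    r <- attn_layer_backward(dX, enc$params$blocks[[l]], fwd$caches[[l]])
    dX <- r$dX
    grads_blocks[[l]] <- r$grads
  }
  demb <- enc$params$emb * 0
  for (t in seq_along(fwd$ids)) {
    demb[fwd$ids[t], ] <- demb[fwd$ids[t], ] + dX[t, ]
  }
  list(emb = demb, blocks = grads_blocks)
}

new_encoded_sequence <- function(vectors, granularity) {
  stopifnot(is.matrix(vectors), all(is.finite(vectors)))
  structure(list(vectors = vectors, granularity = granularity),
            class = "encoded_sequence")
}

encode_tokens <- function(tokens, enc, granularity) {
  if (length(tokens) < 1) stop_bad("cannot encode an empty token sequence")
  if (inherits(enc, "encoder_config")) enc <- build_encoder(enc)
  stopifnot(inherits(enc, "toy_encoder"))
  ids <- tokens_to_ids(tokens, enc$cfg$vocab)
  new_encoded_sequence(encoder_forward(enc, ids)$H, granularity)
}

#' Encode a character sequence
#'
#' Contextually encodes each character of `text`, yielding the M x d
#' matrix of character representations that the rest of the pipeline
#' consumes.
#'
#' @param text a single non-empty string.
#' @param enc a `toy_encoder` (or an [encoder_config()], instantiated on
#'   the fly).
#' @return an `encoded_sequence` with `granularity = "char"`.
#' @export
encode_chars <- function(text, enc) {
  if (!is.character(text) || length(text) != 1L || nchar(text) < 1L) {
    stop_bad("encode_chars needs a single non-empty string")
  }
  encode_tokens(chars_of(text), enc, "char")
}

#' Encode a radical token sequence
#'
#' @param radical_seq character vector of radical tokens (one per source
#'   character), e.g. the output of [decompose()].
#' @inheritParams encode_chars
#' @return an `encoded_sequence` with `granularity = "radical"`.
#' @export
encode_radicals <- function(radical_seq, enc) {
  encode_tokens(radical_seq, enc, "radical")
}

#' Encode a word token sequence
#'
#' @param word_tokens character vector of N segmented words.
#' @inheritParams encode_chars
#' @return an N x d `encoded_sequence` with `granularity = "word"`.
#' @export
encode_words <- function(word_tokens, enc) {
  encode_tokens(word_tokens, enc, "word")
}
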