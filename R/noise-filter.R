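# The text noise-removal model: a BiLSTM feature extractor over the
# character representations followed by a linear-chain CRF over the
# modified BIO alphabet.  The CRF is trained by exact negative
# log-likelihood (forward algorithm) and decoded with Viterbi.

#' Create a linear-chain CRF layer
#'
#' Transition scores are a `(K+2) x (K+2)` matrix: rows/columns `1..K`
#' are the tags, row `K+1` holds start transitions and column `K+2` stop
#' transitions.  A path `y` is scored
#' `sum_i emissions[i, y_i] + start + internal + stop transitions`.
#'
#' @param tag_count number of tags K.
#' @param tags optional character names of the tags (length K).
#' @param seed seed for the small random initialisation of transitions.
#' @return a `crf_layer`.
#' @export
new_crf <- function(tag_count, tags = NULL, seed = 1L) {
  stopifnot(tag_count >= 1)
  trans <- with_seed(seed, rand_mat(tag_count + 2L, tag_count + 2L, scale = 0.01))
  structure(list(tag_count = as.integer(tag_count), tags = tags, trans = trans),
            class = "crf_layer")
}

crf_indices <- function(crf) {
  K <- crf$tag_count
  list(K = K, start = K + 1L, stop = K + 2L)
}

gold_to_indices <- function(gold, crf) {
  if (is.character(gold)) {
    if (is.null(crf$tags)) stop_bad("character gold labels need a CRF with named tags")
    idx <- match(as.character(gold), crf$tags)
    if (anyNA(idx)) {
      stop_bad("gold labels outside the CRF tag alphabet: %s",
               paste(unique(gold[is.na(idx)]), collapse = ", "))
    }
    idx
  } else {
    idx <- as.integer(gold)
    if (any(idx < 1 | idx > crf$tag_count)) stop_bad("gold label index out of range")
    idx
  }
}

crf_path_score <- function(emissions, path, crf) {
  ix <- crf_indices(crf)
  m <- nrow(emissions)
  s <- sum(emissions[cbind(seq_len(m), path)]) +
    crf$trans[ix$start, path[1]] + crf$trans[path[m], ix$stop]
  if (m > 1) {
    s <- s + sum(crf$trans[cbind(path[-m], path[-1])])
  }
  s
}

crf_log_alpha <- function(emissions, crf) {
  ix <- crf_indices(crf)
  m <- nrow(emissions)
  A <- matrix(0, m, ix$K)
  A[1, ] <- emissions[1, ] + crf$trans[ix$start, seq_len(ix$K)]
  if (m > 1) {
    for (t in 2:m) {
      for (j in seq_len(ix$K)) {
        A[t, j] <- logsumexp(A[t - 1, ] + crf$trans[seq_len(ix$K), j]) + emissions[t, j]
      }
    }
  }
  A
}

crf_log_beta <- function(emissions, crf) {
  ix <- crf_indices(crf)
  m <- nrow(emissions)
  B <- matrix(0, m, ix$K)
  B[m, ] <- crf$trans[seq_len(ix$K), ix$stop]
  if (m > 1) {
    for (t in (m - 1):1) {
      for (i in seq_len(ix$K)) {
        B[t, i] <- logsumexp(crf$trans[i, seq_len(ix$K)] + emissions[t + 1, ] + B[t + 1, ])
      }
    }
  }
  B
}

#' CRF negative log-likelihood
#'
#' `loss = log Z - score(gold path)`, where `Z` sums the exponentiated
#' scores of all `K^M` paths (computed by the forward algorithm).  Always
#' `>= 0` and finite for finite scores.
#'
#' @param emissions `M x K` matrix of per-position tag scores.
#' @param gold gold path: integer indices or tag names (if the CRF has
#'   named tags), length `M`.
#' @param crf a [new_crf()] layer.
#' @return scalar loss.
#' @export
crf_nll <- function(emissions, gold, crf) {
  stopifnot(inherits(crf, "crf_layer"), is.matrix(emissions))
  path <- gold_to_indices(gold, crf)
  if (length(path) != nrow(emissions)) stop_bad("gold length != emission rows")
  ix <- crf_indices(crf)
  A <- crf_log_alpha(emissions, crf)
  logZ <- logsumexp(A[nrow(emissions), ] + crf$trans[seq_len(ix$K), ix$stop])
  logZ - crf_path_score(emissions, path, crf)
}

## NLL plus analytic gradients w.r.t. emissions and the transition matrix
## (via forward-backward marginals).  Internal: used by training.
crf_nll_grad <- function(emissions, path, crf) {
  ix <- crf_indices(crf)
  m <- nrow(emissions)
  K <- ix$K
  A <- crf_log_alpha(emissions, crf)
  B <- crf_log_beta(emissions, crf)
  logZ <- logsumexp(A[m, ] + crf$trans[seq_len(K), ix$stop])
  gamma <- exp(A + B - logZ)                       # unary marginals
  dEm <- gamma
  dEm[cbind(seq_len(m), path)] <- dEm[cbind(seq_len(m), path)] - 1
  dTr <- crf$trans * 0
  if (m > 1) {
    for (t in seq_len(m - 1)) {
      xi <- outer(A[t, ], emissions[t + 1, ] + B[t + 1, ], `+`) +
        crf$trans[seq_len(K), seq_len(K)]
      xi <- exp(xi - logZ)
      dTr[seq_len(K), seq_len(K)] <- dTr[seq_len(K), seq_len(K)] + xi
      dTr[path[t], path[t + 1]] <- dTr[path[t], path[t + 1]] - 1
    }
  }
  dTr[ix$start, seq_len(K)] <- gamma[1, ]
  dTr[ix$start, path[1]] <- dTr[ix$start, path[1]] - 1
  dTr[seq_len(K), ix$stop] <- dTr[seq_len(K), ix$stop] + gamma[m, ]
  dTr[path[m], ix$stop] <- dTr[path[m], ix$stop] - 1
  list(loss = logZ - crf_path_score(emissions, path, crf),
       dEm = dEm, dTr = dTr)
}

#' Viterbi decoding
#'
#' Returns an argmax-scoring tag path; score ties are broken towards the
#' lowest tag index, so decoding is fully deterministic.
#'
#' @inheritParams crf_nll
#' @return integer path of length `M`; if the CRF has named tags, a
#'   character vector of tag names (class `tag_sequence`).
#' @export
crf_viterbi <- function(emissions, crf) {
  stopifnot(inherits(crf, "crf_layer"), is.matrix(emissions))
  m <- nrow(emissions)
  if (m < 1) stop_bad("cannot decode an empty sequence")
  ix <- crf_indices(crf)
  K <- ix$K
  delta <- matrix(-Inf, m, K)
  back <- matrix(0L, m, K)
  delta[1, ] <- emissions[1, ] + crf$trans[ix$start, seq_len(K)]
  if (m > 1) {
    for (t in 2:m) {
      for (j in seq_len(K)) {
        cand <- delta[t - 1, ] + crf$trans[seq_len(K), j]
        b <- which.max(cand)           # first max = lowest tag index
        back[t, j] <- b
        delta[t, j] <- cand[b] + emissions[t, j]
      }
    }
  }
  fin <- delta[m, ] + crf$trans[seq_len(K), ix$stop]
  path <- integer(m)
  path[m] <- which.max(fin)
  if (m > 1) {
    for (t in (m - 1):1) path[t] <- back[t + 1, path[t + 1]]
  }
  if (!is.null(crf$tags)) {
    structure(crf$tags[path], class = "tag_sequence")
  } else {
    path
  }
}

#' Initialise BiLSTM parameters
#'
#' @param d_in input width.
#' @param hidden per-direction hidden width `h` (output width is `2h`).
#' @param layers number of stacked bidirectional layers.
#' @param seed seed for initialisation.
#' @return a parameter tree for [bilstm_encode()].
#' @export
bilstm_params <- function(d_in, hidden, layers = 2L, seed = 1L) {
  with_seed(seed, bilstm_stack_init(d_in, hidden, layers))
}

#' BiLSTM feature extraction
#'
#' Runs a stacked bidirectional LSTM over character representations,
#' concatenating the forward and backward hidden states at every
#' position (width `2h`).
#'
#' @param H_c an `encoded_sequence` (character granularity) or a plain
#'   `M x d` matrix.
#' @param params parameters from [bilstm_params()].
#' @return an `encoded_sequence` of shape `M x 2h`.
#' @export
bilstm_encode <- function(H_c, params) {
  X <- if (inherits(H_c, "encoded_sequence")) H_c$vectors else H_c
  stopifnot(is.matrix(X))
  new_encoded_sequence(bilstm_stack_forward(X, params)$H, "char")
}

## ---- denoiser model -------------------------------------------------------

denoiser_forward <- function(params, ids, cache = FALSE) {
  enc <- structure(list(cfg = params$enc_cfg, params = params$enc),
                   class = "toy_encoder")
  ef <- encoder_forward(enc, ids, cache = cache)
  bf <- bilstm_stack_forward(ef$H, params$lstm)
  em <- bf$H %*% params$proj$W + matrix(params$proj$b, nrow(bf$H),
                                        length(params$proj$b), byrow = TRUE)
  list(emissions = em, enc_fwd = ef, bi_fwd = bf, H_bi = bf$H)
}

#' Train the text noise-removal model
#'
#' Fits a character encoder + BiLSTM + CRF sequence labeler that assigns
#' each character a modified BIO tag (see [tag_alphabet()]), separating
#' domain-relevant entities from distractors.  Training minimises the CRF
#' negative log-likelihood with Adam; it is deterministic given `seed`.
#'
#' @param corpus list of [annotated_sentence()] objects; gold tags are
#'   derived with [encode_tags()].
#' @param dim character embedding width.
#' @param hidden per-direction LSTM width.
#' @param lstm_layers stacked BiLSTM layers (default 2; larger stacks as
#'   in heavy-duty configurations are available but rarely needed at toy
#'   scale).
#' @param enc_layers attention blocks in the character encoder feeding
#'   the BiLSTM (default 0: the recurrence supplies the context).
#' @param epochs,lr,batch_size optimisation hyperparameters (Adam).
#' @param seed integer seed controlling initialisation and shuffling.
#' @param verbose print per-epoch mean NLL?
#' @return a `denoiser_model` with fields `params`, `crf`, `vocab`,
#'   `loss_log`.
#' @export
train_denoiser <- function(corpus, dim = 24L, hidden = 16L, lstm_layers = 2L,
                           enc_layers = 0L, epochs = 25L, lr = 3e-3,
                           batch_size = 16L, seed = 1L, verbose = FALSE) {
  if (length(corpus) == 0) stop_bad("cannot train on an empty corpus")
  tags <- tag_alphabet()
  K <- length(tags)
  vocab <- make_vocab(unlist(lapply(corpus, function(s) chars_of(s$text))))
  enc_cfg <- encoder_config(vocab, dim = dim, layers = enc_layers,
                            seed = derive_seed(seed, 1))
  enc <- build_encoder(enc_cfg)
  crf <- new_crf(K, tags = tags, seed = derive_seed(seed, 2))
  params <- list(
    enc = enc$params,
    lstm = with_seed(derive_seed(seed, 3), bilstm_stack_init(dim, hidden, lstm_layers)),
    proj = with_seed(derive_seed(seed, 4),
                     list(W = rand_mat(2 * hidden, K), b = numeric(K))),
    trans = crf$trans
  )
  params$enc_cfg <- NULL
  golds <- lapply(corpus, function(s) match(as.character(encode_tags(s)), tags))
  idlists <- lapply(corpus, function(s) tokens_to_ids(chars_of(s$text), vocab))
  st <- adam_init(params)
  loss_log <- numeric(epochs)
  with_seed(derive_seed(seed, 5), {
    for (ep in seq_len(epochs)) {
      ord <- sample(seq_along(corpus))
      total <- 0
      bstart <- 1L
      while (bstart <= length(ord)) {
        bidx <- ord[bstart:min(bstart + batch_size - 1L, length(ord))]
        grads <- zeros_like(params)
        for (si in bidx) {
          fwd <- denoiser_forward(c(params, list(enc_cfg = enc_cfg)), idlists[[si]],
                                  cache = TRUE)
          cg <- crf_nll_grad(fwd$emissions,
                             golds[[si]],
                             structure(list(tag_count = K, tags = tags,
                                            trans = params$trans),
                                       class = "crf_layer"))
          total <- total + cg$loss
          dW <- t(fwd$H_bi) %*% cg$dEm
          db <- colSums(cg$dEm)
          dH <- cg$dEm %*% t(params$proj$W)
          bb <- bilstm_stack_backward(dH, params$lstm, fwd$bi_fwd$caches)
          denc <- encoder_backward(enc, fwd$enc_fwd, bb$dX)
          g <- list(enc = denc, lstm = bb$grads,
                    proj = list(W = dW, b = db), trans = cg$dTr)
          grads <- tree_add(grads, g)
        }
        grads <- tree_scale(grads, 1 / length(bidx))
        r <- adam_step(params, grads, st, lr = lr)
        params <- r$params
        st <- r$state
        ## keep the encoder object in sync for the next forward pass
        enc$params <- params$enc
        bstart <- bstart + batch_size
      }
      loss_log[ep] <- total / length(corpus)
      if (verbose) message(sprintf("denoiser epoch %d: mean NLL %.4f", ep, loss_log[ep]))
    }
  })
  structure(list(params = params, enc_cfg = enc_cfg,
                 crf = structure(list(tag_count = K, tags = tags,
                                      trans = params$trans),
                                 class = "crf_layer"),
                 vocab = vocab, loss_log = loss_log,
                 cfg = list(dim = dim, hidden = hidden, lstm_layers = lstm_layers,
                            enc_layers = enc_layers, epochs = epochs, lr = lr,
                            batch_size = batch_size, seed = seed)),
            class = "denoiser_model")
}

#' Predict modified BIO tags for a sentence
#'
#' @param model a `denoiser_model` from [train_denoiser()].
#' @param text a sentence string (or an [annotated_sentence()]).
#' @return a `tag_sequence` over [tag_alphabet()].
#' @export
predict_tags <- function(model, text) {
  stopifnot(inherits(model, "denoiser_model"))
  if (inherits(text, "annotated_sentence")) text <- text$text
  ids <- tokens_to_ids(chars_of(text), model$vocab)
  fwd <- denoiser_forward(c(model$params, list(enc_cfg = model$enc_cfg)), ids)
  crf_viterbi(fwd$emissions, model$crf)
}

#' Tag accuracy of a denoiser on a corpus
#'
#' @param model a `denoiser_model`.
#' @param corpus list of annotated sentences with gold annotations.
#' @return fraction of positions whose predicted tag equals the gold tag.
#' @export
denoiser_accuracy <- function(model, corpus) {
  hit <- 0; tot <- 0
  for (s in corpus) {
    gold <- as.character(encode_tags(s))
    pred <- as.character(predict_tags(model, s))
    hit <- hit + sum(gold == pred)
    tot <- tot + length(gold)
  }
  hit / tot
}
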