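# The cascading pointer extractor.  A subject marker (two position-wise
# binary classifiers) proposes subject spans; for every candidate
# subject, per-relation object taggers -- again head/tail binary
# classifiers, one pair per target relation -- mark that subject's
# objects, so triples that share a subject (overlapping triples) are
# recovered naturally.  Training minimises mean binary cross-entropy
# over all pointer positions with one randomly sampled gold subject
# conditioning the object taggers at each step.

#' Configure the cascade extractor
#'
#' @param tau decoding threshold in (0,1) for head/tail probabilities
#'   (default 0.5; decoding is strict: a probability equal to `tau` does
#'   not fire).
#' @param max_subjects cap on candidate subjects per sentence.
#' @param dim_char,dim_radical,dim_word embedding widths of the three
#'   encoders.
#' @param enc_layers_char,enc_layers_radical,enc_layers_word attention
#'   blocks per encoder.
#' @param use_radical,use_word include the radical / word fusion streams?
#' @param use_mask gate representations with the noise-filter mask?
#' @param mask_policy passed to [position_mask()].
#' @param post_filter drop decoded triples whose subject or object lies
#'   wholly in mask-zeroed positions?
#' @param subject_pool how a subject span is summarised before being
#'   added to every position: `"mean"` of its rows (default) or `"head"`
#'   (first row only).
#' @param include_other train an object tagger for the residual "Other"
#'   relation too? (Off by default: "Other" marks noise, not a target.)
#' @param teacher_force_mask during training, build the mask from gold
#'   tags (default) rather than from a denoiser's predictions.
#' @param epochs,lr,batch_size Adam training hyperparameters.
#' @param pos_weight weight applied to positive (head/tail = 1) terms of
#'   the binary cross-entropy.  Pointer labels are extremely sparse (a
#'   handful of 1s among hundreds of positions), and an unweighted loss
#'   lets small models collapse onto the all-zero prediction; the
#'   default up-weights positives enough to escape that optimum.
#' @param seed master seed for initialisation, shuffling and subject
#'   sampling.
#' @return an `extractor_config` list.
#' @export
extractor_config <- function(tau = 0.5, max_subjects = 8L,
                             dim_char = 32L, dim_radical = 16L, dim_word = 16L,
                             enc_layers_char = 2L, enc_layers_radical = 1L,
                             enc_layers_word = 1L,
                             use_radical = TRUE, use_word = TRUE,
                             use_mask = TRUE,
                             mask_policy = "keep_outside",
                             post_filter = TRUE,
                             subject_pool = c("mean", "head"),
                             include_other = FALSE,
                             teacher_force_mask = TRUE,
                             epochs = 30L, lr = 5e-3, batch_size = 16L,
                             pos_weight = 10, seed = 1L) {
  stopifnot(tau > 0, tau < 1, pos_weight > 0)
  structure(list(tau = tau, max_subjects = as.integer(max_subjects),
                 dim_char = as.integer(dim_char),
                 dim_radical = as.integer(dim_radical),
                 dim_word = as.integer(dim_word),
                 enc_layers_char = as.integer(enc_layers_char),
                 enc_layers_radical = as.integer(enc_layers_radical),
                 enc_layers_word = as.integer(enc_layers_word),
                 use_radical = use_radical, use_word = use_word,
                 use_mask = use_mask, mask_policy = mask_policy,
                 post_filter = post_filter,
                 subject_pool = match.arg(subject_pool),
                 include_other = include_other,
                 teacher_force_mask = teacher_force_mask,
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 pos_weight = pos_weight,
                 seed = as.integer(seed)),
            class = "extractor_config")
}

#' Subject marker scores
#'
#' Position-wise head/tail probabilities `sigma(H_cw[i, ] . w + b)`.
#'
#' @param H_cw a `fused_sequence` (or `M x D` matrix).
#' @param params list with `W` (`D x 2`: head and tail columns) and `b`
#'   (length 2).
#' @return list with numeric vectors `head` and `tail`, entries in (0,1).
#' @export
subject_scores <- function(H_cw, params) {
  X <- if (inherits(H_cw, "fused_sequence")) H_cw$vectors else H_cw
  L <- X %*% params$W + matrix(params$b, nrow(X), 2, byrow = TRUE)
  P <- sigmoid(L)
  list(head = P[, 1], tail = P[, 2])
}

#' Decode spans from head/tail probability vectors
#'
#' Positions with `head > tau` open spans; each start is paired with the
#' nearest position `>= start` whose tail probability exceeds `tau`
#' (nearest-tail pairing); starts with no such tail are dropped.  Spans
#' are returned 0-based half-open, so a head at position `i` paired with
#' a tail at position `j` yields `[i, j + 1)`.
#'
#' @param head,tail numeric probability vectors of equal length.
#' @param tau threshold; comparison is strict.
#' @return list of integer `c(start, end)` pairs.
#' @export
decode_spans <- function(head, tail, tau) {
  stopifnot(length(head) == length(tail))
  starts <- which(head > tau)
  tails <- which(tail > tau)
  spans <- list()
  for (s in starts) {
    t <- tails[tails >= s]
    if (length(t) > 0) {
      spans[[length(spans) + 1L]] <- c(s - 1L, t[1])
    }
  }
  spans
}

#' Condition the fused representation on a candidate subject
#'
#' Summarises the subject span (mean of its rows by default) and adds
#' the summary vector to every position, yielding the subject-aware
#' representation the object taggers score.
#'
#' @param H_cw a `fused_sequence` (or matrix).
#' @param span integer `c(start, end)`, 0-based half-open.
#' @param pool `"mean"` or `"head"`.
#' @return a `fused_sequence` of the same shape.
#' @export
condition_subject <- function(H_cw, span, pool = c("mean", "head")) {
  pool <- match.arg(pool)
  X <- if (inherits(H_cw, "fused_sequence")) H_cw$vectors else H_cw
  if (span[1] < 0 || span[2] > nrow(X) || span[2] <= span[1]) {
    stop_bad("invalid subject span [%d, %d) for %d positions", span[1], span[2], nrow(X))
  }
  rows <- (span[1] + 1L):span[2]
  v <- if (pool == "mean") colMeans(X[rows, , drop = FALSE]) else X[rows[1], ]
  out <- X + matrix(v, nrow(X), ncol(X), byrow = TRUE)
  parts <- if (inherits(H_cw, "fused_sequence")) H_cw$parts else c(all = ncol(X))
  new_fused_sequence(out, parts)
}

#' Per-relation object tagger scores
#'
#' One head/tail classifier pair per target relation, all applied
#' position-wise to the subject-conditioned representation.
#'
#' @param H_hat a subject-conditioned `fused_sequence` (or matrix).
#' @param params list with `W` (`D x 2R`; columns `2r-1`, `2r` are
#'   relation `r`'s head and tail), `b` (length `2R`) and `rels`
#'   (character vector of the R relation abbreviations).
#' @return list with `head` and `tail`, each an `R x M` probability
#'   matrix with rownames `params$rels`.
#' @export
object_scores <- function(H_hat, params) {
  X <- if (inherits(H_hat, "fused_sequence")) H_hat$vectors else H_hat
  L <- X %*% params$W + matrix(params$b, nrow(X), length(params$b), byrow = TRUE)
  P <- sigmoid(L)                      # M x 2R
  R <- length(params$rels)
  head <- t(P[, 2 * seq_len(R) - 1L, drop = FALSE])
  tail <- t(P[, 2 * seq_len(R), drop = FALSE])
  rownames(head) <- rownames(tail) <- params$rels
  list(head = head, tail = tail)
}

## ---- feature pipeline -----------------------------------------------------

## Which mask/tags to use for a sentence.
sentence_mask <- function(model, sentence, mask_source) {
  cfg <- model$cfg
  m <- nchar(sentence$text)
  if (!isTRUE(cfg$use_mask) || mask_source == "none") {
    return(rep(1, m))
  }
  tags <- switch(mask_source,
    gold = encode_tags(sentence),
    predicted = {
      if (is.null(model$denoiser)) stop_bad("no denoiser attached: cannot use predicted mask")
      predict_tags(model$denoiser, sentence$text)
    },
    stop_bad("unknown mask source '%s'", mask_source)
  )
  position_mask(tags, cfg$mask_policy)
}

## Build H_cw for a sentence; with cache = TRUE keep everything needed
## for backpropagation.
extractor_features <- function(model, sentence, mask_source, cache = FALSE) {
  cfg <- model$cfg
  text <- sentence$text
  E <- sentence_mask(model, sentence, mask_source)
  enc_c <- structure(list(cfg = model$enc_cfgs$char, params = model$params$enc_c),
                     class = "toy_encoder")
  ids_c <- tokens_to_ids(chars_of(text), model$enc_cfgs$char$vocab)
  fc <- encoder_forward(enc_c, ids_c, cache = cache)
  blocks <- list(char = fc$H * E)
  fr <- fw <- seg <- NULL
  if (isTRUE(cfg$use_radical)) {
    enc_r <- structure(list(cfg = model$enc_cfgs$radical, params = model$params$enc_r),
                       class = "toy_encoder")
    ids_r <- tokens_to_ids(decompose(text, model$radical_table),
                           model$enc_cfgs$radical$vocab)
    fr <- encoder_forward(enc_r, ids_r, cache = cache)
    blocks$radical <- fr$H * E
  }
  if (isTRUE(cfg$use_word)) {
    enc_w <- structure(list(cfg = model$enc_cfgs$word, params = model$params$enc_w),
                       class = "toy_encoder")
    seg <- segment(text, model$lexicon)
    ids_w <- tokens_to_ids(seg$tokens, model$enc_cfgs$word$vocab)
    fw <- encoder_forward(enc_w, ids_w, cache = cache)
    blocks$word <- fw$H[seg$char_to_word, , drop = FALSE] * E
  }
  H <- do.call(cbind, blocks)
  list(H = H, E = E, fc = fc, fr = fr, fw = fw, seg = seg,
       widths = vapply(blocks, ncol, integer(1)))
}

## Push dH (M x D) back through fusion and the three encoders; returns a
## gradient tree matching model$params for the encoder components.
extractor_features_backward <- function(model, feats, dH) {
  w <- feats$widths
  off <- 0L
  enc_c <- structure(list(cfg = model$enc_cfgs$char, params = model$params$enc_c),
                     class = "toy_encoder")
  dHc <- dH[, (off + 1):(off + w[["char"]]), drop = FALSE] * feats$E
  off <- off + w[["char"]]
  g <- list(enc_c = encoder_backward(enc_c, feats$fc, dHc))
  if (!is.null(feats$fr)) {
    enc_r <- structure(list(cfg = model$enc_cfgs$radical, params = model$params$enc_r),
                       class = "toy_encoder")
    dHr <- dH[, (off + 1):(off + w[["radical"]]), drop = FALSE] * feats$E
    off <- off + w[["radical"]]
    g$enc_r <- encoder_backward(enc_r, feats$fr, dHr)
  }
  if (!is.null(feats$fw)) {
    enc_w <- structure(list(cfg = model$enc_cfgs$word, params = model$params$enc_w),
                       class = "toy_encoder")
    dHwe <- dH[, (off + 1):(off + w[["word"]]), drop = FALSE] * feats$E
    dHw <- matrix(0, length(feats$seg$tokens), w[["word"]])
    for (i in seq_along(feats$seg$char_to_word)) {
      j <- feats$seg$char_to_word[i]
      dHw[j, ] <- dHw[j, ] + dHwe[i, ]
    }
    g$enc_w <- encoder_backward(enc_w, feats$fw, dHw)
  }
  g
}

## ---- loss and training ----------------------------------------------------

useful_subject_spans <- function(sentence) {
  spans <- list()
  seen <- character(0)
  for (tr in sentence$triples) {
    if (!tr$useful) next
    key <- sprintf("%d-%d", tr$subj$start, tr$subj$end)
    if (!key %in% seen) {
      seen <- c(seen, key)
      spans[[length(spans) + 1L]] <- c(tr$subj$start, tr$subj$end)
    }
  }
  spans
}

pointer_labels <- function(m, spans) {
  Y <- matrix(0, m, 2)
  for (sp in spans) {
    Y[sp[1] + 1L, 1] <- 1
    Y[sp[2], 2] <- 1
  }
  Y
}

## Loss (and optionally gradients) for one sentence.  The object taggers
## are conditioned on one gold subject sampled from the sentence's
## useful triples (standard cascade training regime).
extractor_sentence_loss <- function(model, sentence, grad = FALSE,
                                    mask_source = NULL) {
  cfg <- model$cfg
  mask_source <- mask_source %||% (if (isTRUE(cfg$teacher_force_mask)) "gold" else "predicted")
  feats <- extractor_features(model, sentence, mask_source, cache = grad)
  H <- feats$H
  m <- nrow(H)
  rels <- model$rels
  R <- length(rels)
  subj_spans <- useful_subject_spans(sentence)
  Ysub <- pointer_labels(m, subj_spans)
  Ps <- sigmoid(H %*% model$params$sub$W +
                  matrix(model$params$sub$b, m, 2, byrow = TRUE))
  ## positive terms carry weight pos_weight; loss is normalised by the
  ## total weight, so uniform p = 0.5 always gives exactly log 2
  w <- cfg$pos_weight %||% 1
  Wsub <- 1 + (w - 1) * Ysub
  n_terms <- sum(Wsub)
  loss_sum <- {
    p <- clip_prob(Ps)
    -sum(Wsub * (Ysub * log(p) + (1 - Ysub) * log(1 - p)))
  }
  picked <- NULL
  if (length(subj_spans) > 0 && R > 0) {
    picked <- subj_spans[[sample.int(length(subj_spans), 1L)]]
    rows <- (picked[1] + 1L):picked[2]
    v <- if (cfg$subject_pool == "mean") colMeans(H[rows, , drop = FALSE]) else H[rows[1], ]
    Hhat <- H + matrix(v, m, ncol(H), byrow = TRUE)
    Yobj <- matrix(0, m, 2 * R)
    for (tr in sentence$triples) {
      if (!tr$useful) next
      if (tr$subj$start != picked[1] || tr$subj$end != picked[2]) next
      r <- match(tr$rel, rels)
      if (is.na(r)) next
      Yobj[tr$obj$start + 1L, 2 * r - 1L] <- 1
      Yobj[tr$obj$end, 2 * r] <- 1
    }
    Po <- sigmoid(Hhat %*% model$params$obj$W +
                    matrix(model$params$obj$b, m, 2 * R, byrow = TRUE))
    po <- clip_prob(Po)
    Wobj <- 1 + (w - 1) * Yobj
    loss_sum <- loss_sum - sum(Wobj * (Yobj * log(po) + (1 - Yobj) * log(1 - po)))
    n_terms <- n_terms + sum(Wobj)
  }
  loss <- loss_sum / n_terms
  if (!grad) return(list(loss = loss))
  ## ---- backward ----
  dLs <- Wsub * (Ps - Ysub) / n_terms                # M x 2
  gsub <- list(W = t(H) %*% dLs, b = colSums(dLs))
  dH <- dLs %*% t(model$params$sub$W)
  gobj <- list(W = model$params$obj$W * 0, b = model$params$obj$b * 0)
  if (!is.null(picked)) {
    dLo <- Wobj * (Po - Yobj) / n_terms              # M x 2R
    gobj$W <- t(Hhat) %*% dLo
    gobj$b <- colSums(dLo)
    dHhat <- dLo %*% t(model$params$obj$W)
    dH <- dH + dHhat
    dv <- colSums(dHhat)
    rows <- (picked[1] + 1L):picked[2]
    if (cfg$subject_pool == "mean") {
      dH[rows, ] <- dH[rows, , drop = FALSE] +
        matrix(dv / length(rows), length(rows), ncol(H), byrow = TRUE)
    } else {
      dH[rows[1], ] <- dH[rows[1], ] + dv
    }
  }
  genc <- extractor_features_backward(model, feats, dH)
  grads <- c(genc, list(sub = gsub, obj = gobj))
  ## gradient tree must mirror the parameter tree's element order
  grads <- grads[names(model$params)]
  list(loss = loss, grads = grads)
}

#' Mean pointer-tagging loss of a batch
#'
#' Mean binary cross-entropy over subject head/tail and all relations'
#' object head/tail position labels, with one gold subject sampled per
#' sentence to condition the object taggers.  Uses the current RNG
#' stream for the subject sampling.
#'
#' @param batch list of [annotated_sentence()] objects.
#' @param model an `extractor_model`.
#' @return scalar mean loss (>= 0).
#' @export
training_loss <- function(batch, model) {
  stopifnot(length(batch) > 0)
  mean(vapply(batch, function(s) extractor_sentence_loss(model, s)$loss, numeric(1)))
}

init_extractor_model <- function(schema, cfg, radical_table, lexicon,
                                 corpus, denoiser = NULL) {
  chars <- unlist(lapply(corpus, function(s) chars_of(s$text)))
  vocab_c <- make_vocab(chars)
  rels <- relation_abbrevs(schema, include_other = cfg$include_other)
  enc_cfgs <- list(char = encoder_config(vocab_c, dim = cfg$dim_char,
                                         layers = cfg$enc_layers_char,
                                         seed = derive_seed(cfg$seed, 11)))
  params <- list()
  if (isTRUE(cfg$use_radical)) {
    rads <- unlist(lapply(corpus, function(s) decompose(s$text, radical_table)))
    enc_cfgs$radical <- encoder_config(make_vocab(rads), dim = cfg$dim_radical,
                                       layers = cfg$enc_layers_radical,
                                       seed = derive_seed(cfg$seed, 12))
    params$enc_r <- build_encoder(enc_cfgs$radical)$params
  }
  if (isTRUE(cfg$use_word)) {
    words <- unlist(lapply(corpus, function(s) segment(s$text, lexicon)$tokens))
    enc_cfgs$word <- encoder_config(make_vocab(words), dim = cfg$dim_word,
                                    layers = cfg$enc_layers_word,
                                    seed = derive_seed(cfg$seed, 13))
    params$enc_w <- build_encoder(enc_cfgs$word)$params
  }
  params$enc_c <- build_encoder(enc_cfgs$char)$params
  D <- cfg$dim_char +
    (if (isTRUE(cfg$use_radical)) cfg$dim_radical else 0L) +
    (if (isTRUE(cfg$use_word)) cfg$dim_word else 0L)
  params$sub <- with_seed(derive_seed(cfg$seed, 14),
                          list(W = rand_mat(D, 2), b = numeric(2)))
  params$obj <- with_seed(derive_seed(cfg$seed, 15),
                          list(W = rand_mat(D, 2 * length(rels)),
                               b = numeric(2 * length(rels))))
  structure(list(type = "neural", cfg = cfg, schema = schema, rels = rels,
                 radical_table = radical_table, lexicon = lexicon,
                 enc_cfgs = enc_cfgs, params = params, denoiser = denoiser,
                 loss_log = numeric(0)),
            class = "extractor_model")
}

#' Train the cascade extractor
#'
#' End-to-end Adam training of the three toy encoders and the subject /
#' per-relation object pointer taggers, deterministic given `cfg$seed`.
#' During training the noise mask is teacher-forced from gold tags by
#' default; at inference it comes from the attached denoiser's
#' predictions.
#'
#' @param corpus non-empty list of [annotated_sentence()] objects.
#' @param schema a `relation_schema`.
#' @param cfg an [extractor_config()].
#' @param radical_table a [radical_table()] (required if
#'   `cfg$use_radical`).
#' @param lexicon word list for segmentation (required if
#'   `cfg$use_word`).
#' @param denoiser optional `denoiser_model` used for predicted masks at
#'   inference time.
#' @param verbose print per-epoch mean loss?
#' @return an `extractor_model` with a per-epoch `loss_log`.
#' @export
train_extractor <- function(corpus, schema, cfg = extractor_config(),
                            radical_table = NULL, lexicon = NULL,
                            denoiser = NULL, verbose = FALSE) {
  if (length(corpus) == 0) stop_bad("cannot train on an empty corpus")
  if (isTRUE(cfg$use_radical) && is.null(radical_table)) {
    stop_bad("use_radical = TRUE needs a radical_table")
  }
  if (isTRUE(cfg$use_word) && is.null(lexicon)) {
    stop_bad("use_word = TRUE needs a lexicon")
  }
  model <- init_extractor_model(schema, cfg, radical_table, lexicon, corpus,
                                denoiser = denoiser)
  st <- adam_init(model$params)
  loss_log <- numeric(cfg$epochs)
  with_seed(derive_seed(cfg$seed, 20), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(seq_along(corpus))
      total <- 0
      bstart <- 1L
      while (bstart <= length(ord)) {
        bidx <- ord[bstart:min(bstart + cfg$batch_size - 1L, length(ord))]
        grads <- zeros_like(model$params)
        for (si in bidx) {
          r <- extractor_sentence_loss(model, corpus[[si]], grad = TRUE)
          total <- total + r$loss
          grads <- tree_add(grads, r$grads)
        }
        grads <- tree_scale(grads, 1 / length(bidx))
        a <- adam_step(model$params, grads, st, lr = cfg$lr)
        model$params <- a$params
        st <- a$state
        bstart <- bstart + cfg$batch_size
      }
      loss_log[ep] <- total / length(corpus)
      if (verbose) message(sprintf("extractor epoch %d: mean loss %.5f", ep, loss_log[ep]))
    }
  })
  model$loss_log <- loss_log
  model
}

## ---- inference ------------------------------------------------------------

#' Build a gold-score oracle extractor
#'
#' An extractor whose pointer scores are one-hot encodings of a
#' sentence's own gold annotations.  It exercises exactly the same span
#' decoding, cascading, and post-filter path as a trained model, so it
#' serves as a decoder-correctness oracle and for worked examples.
#'
#' @param schema a `relation_schema`.
#' @param cfg an [extractor_config()]; `use_mask`/`post_filter` control
#'   whether the gold noise filter is applied on top of decoding.
#' @return an `extractor_model` of type `"oracle"`.
#' @export
gold_score_model <- function(schema, cfg = extractor_config(use_mask = FALSE,
                                                            post_filter = FALSE)) {
  structure(list(type = "oracle", cfg = cfg, schema = schema,
                 denoiser = NULL),
            class = "extractor_model")
}

oracle_scores <- function(sentence, rels) {
  m <- nchar(sentence$text)
  sub_head <- numeric(m); sub_tail <- numeric(m)
  for (tr in sentence$triples) {
    sub_head[tr$subj$start + 1L] <- 1
    sub_tail[tr$subj$end] <- 1
  }
  obj_for <- function(span) {
    head <- matrix(0, length(rels), m, dimnames = list(rels, NULL))
    tail <- head
    for (tr in sentence$triples) {
      if (tr$subj$start == span[1] && tr$subj$end == span[2] && tr$rel %in% rels) {
        head[tr$rel, tr$obj$start + 1L] <- 1
        tail[tr$rel, tr$obj$end] <- 1
      }
    }
    list(head = head, tail = tail)
  }
  list(sub_head = sub_head, sub_tail = sub_tail, obj_for = obj_for)
}

#' Extract triples from a sentence
#'
#' Runs the full pipeline: encode characters, obtain the noise mask
#' (from the denoiser's predicted tags, or gold tags), build the fused
#' representation, decode candidate subjects, and for each subject
#' decode per-relation objects.  With `cfg$post_filter`, decoded triples
#' whose subject or object lies wholly in mask-zeroed positions are
#' dropped.
#'
#' @param sentence an [annotated_sentence()] (gold triples are ignored
#'   by neural models and used as the score source by oracle models).
#' @param model an `extractor_model`.
#' @param cfg optional [extractor_config()] overriding `model$cfg`.
#' @param mask_source `"auto"` (predicted if a denoiser is attached,
#'   else gold), `"predicted"`, `"gold"`, or `"none"`.
#' @return list of [triple()] objects.
#' @export
extract_triples <- function(sentence, model, cfg = NULL,
                            mask_source = c("auto", "predicted", "gold", "none")) {
  mask_source <- match.arg(mask_source)
  cfg <- cfg %||% model$cfg
  m <- nchar(sentence$text)
  if (m < 1) stop_bad("cannot extract from an empty sentence")
  if (mask_source == "auto") {
    mask_source <- if (!is.null(model$denoiser)) "predicted" else "gold"
  }
  if (model$type == "oracle") {
    rels <- relation_abbrevs(model$schema, include_other = cfg$include_other)
    sc <- oracle_scores(sentence, rels)
    subj_spans <- decode_spans(sc$sub_head, sc$sub_tail, cfg$tau)
    E <- if (isTRUE(cfg$use_mask) || isTRUE(cfg$post_filter)) {
      position_mask(encode_tags(sentence), cfg$mask_policy)
    } else rep(1, m)
    get_obj <- function(span) sc$obj_for(span)
  } else {
    model2 <- model
    model2$cfg <- cfg
    feats <- extractor_features(model2, sentence, mask_source)
    E <- feats$E
    ps <- subject_scores(feats$H, model$params$sub)
    subj_spans <- decode_spans(ps$head, ps$tail, cfg$tau)
    rels <- model$rels
    get_obj <- function(span) {
      Hhat <- condition_subject(feats$H, span, pool = cfg$subject_pool)
      object_scores(Hhat, c(model$params$obj, list(rels = rels)))
    }
  }
  if (length(subj_spans) > cfg$max_subjects) {
    subj_spans <- subj_spans[seq_len(cfg$max_subjects)]
  }
  masked_out <- function(span) {
    isTRUE(cfg$post_filter) && all(E[(span[1] + 1L):span[2]] == 0)
  }
  out <- list()
  for (sp in subj_spans) {
    osc <- get_obj(sp)
    for (r in seq_along(rels)) {
      ospans <- decode_spans(osc$head[r, ], osc$tail[r, ], cfg$tau)
      for (osp in ospans) {
        if (masked_out(sp) || masked_out(osp)) next
        out[[length(out) + 1L]] <- triple(sp, rels[r], osp)
      }
    }
  }
  out
}

#' Extract triples for a whole corpus
#'
#' @param corpus list of annotated sentences.
#' @inheritParams extract_triples
#' @return named list (by sentence id) of triple lists.
#' @export
extract_corpus <- function(corpus, model, cfg = NULL, mask_source = "auto") {
  out <- lapply(corpus, extract_triples, model = model, cfg = cfg,
                mask_source = mask_source)
  names(out) <- vapply(corpus, `[[`, character(1), "id")
  out
}
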