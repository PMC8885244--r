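# Synthetic toy language and corpus generator.  The toy language mimics
# the structure the pipeline is built for: sentences are concatenations
# of clause patterns "SUBJECT connector OBJECT" separated by filler
# words, where every relation has its own connector word, entities are
# multi-character lexicon words, and every character decomposes into a
# small radical alphabet shared by several characters.  Distractor
# (Noise) clauses draw on the *same* entity vocabulary as relevant
# clauses and are signalled only by a preceding background-marker word:
# relevance is contextual, as in real monitoring text, so it is
# learnable by the densely supervised sequence labeler but cannot be
# read off an entity's characters.  Because the characters live in the
# CJK block, the real code path (NFC, UTF-8 handling, radical lookup,
# segmentation) is exercised end to end.

toy_chars <- function(n, offset = 0L) {
  vapply(seq_len(n), function(i) intToUtf8(0x4E00 + offset + i - 1L), character(1))
}

#' Build a toy language
#'
#' Deterministic given `seed`.  The language consists of a character
#' alphabet partitioned into roles (entity characters, background-marker
#' characters, filler characters, connector characters), a radical table
#' mapping every character onto a small radical alphabet (characters of
#' one role share role-specific radicals, and radicals map to
#' themselves), a lexicon of entity / marker / filler words with
#' per-word type tags, a relation schema with one connector word per
#' relation plus the residual "Other", and implicit clause templates
#' `SUBJ conn OBJ` (prefixed by a marker word when the clause is a
#' distractor).
#'
#' @param seed integer seed.
#' @param sizes optional named list overriding the defaults:
#'   `n_chars` (total alphabet size, default 60), `n_radicals` (default
#'   8), `n_relations` (target relations, default 4), `n_entity_words`
#'   (default 24), `n_marker_words` (default 3), `n_filler_words`
#'   (default 16).
#' @return a `toy_language`.
#' @export
make_toy_language <- function(seed = 1L, sizes = list()) {
  sz <- utils::modifyList(list(n_chars = 60L, n_radicals = 8L, n_relations = 4L,
                               n_entity_words = 24L, n_marker_words = 3L,
                               n_filler_words = 16L), sizes)
  stopifnot(all(unlist(sz) > 0))
  if (sz$n_chars < sz$n_radicals) {
    stop_bad("alphabet (%d) smaller than radical count (%d)", sz$n_chars, sz$n_radicals)
  }
  n_conn_chars <- min(2L * (sz$n_relations + 1L), max(2L, sz$n_chars %/% 6L))
  remaining <- sz$n_chars - n_conn_chars
  n_entity_chars <- max(1L, round(remaining * 0.62))
  n_marker_chars <- max(1L, round(remaining * 0.12))
  n_filler_chars <- remaining - n_entity_chars - n_marker_chars
  if (n_filler_chars < 1L) stop_bad("alphabet too small to split into roles")

  alphabet <- toy_chars(sz$n_chars)
  roles <- rep(c("entity", "marker", "filler", "connector"),
               c(n_entity_chars, n_marker_chars, n_filler_chars, n_conn_chars))
  radicals <- toy_chars(sz$n_radicals, offset = 4096L)

  ## role-specific radical pools: entity characters never share a radical
  ## with function-word characters, so the radical stream is informative
  pool_of <- function(role) {
    k <- sz$n_radicals
    switch(role,
           entity = radicals[seq_len(max(1L, floor(k * 0.5)))],
           marker = radicals[max(1L, floor(k * 0.5) + 1L)],
           filler = radicals[(floor(k * 0.5) + 2L):max(floor(k * 0.5) + 2L, k - 1L)],
           connector = radicals[k])
  }

  with_seed(seed, {
    mapping <- character(0)
    for (role in unique(roles)) {
      chars <- alphabet[roles == role]
      pool <- pool_of(role)
      ## round-robin base assignment guarantees every pool radical is used
      assigned <- pool[((seq_along(chars) - 1L) %% length(pool)) + 1L]
      mapping[chars] <- sample(assigned)
    }
    mapping[radicals] <- radicals          # radicals decompose to themselves

    entity_chars <- alphabet[roles == "entity"]
    marker_chars <- alphabet[roles == "marker"]
    filler_chars <- alphabet[roles == "filler"]
    conn_chars <- alphabet[roles == "connector"]

    make_words <- function(chars, n, len_range) {
      words <- character(0)
      guard <- 0L
      while (length(words) < n && guard < 50L * n) {
        guard <- guard + 1L
        len <- sample(len_range[1]:len_range[2], 1L)
        w <- paste(sample(chars, len, replace = TRUE), collapse = "")
        if (!w %in% words) words <- c(words, w)
      }
      words
    }
    entity_words <- make_words(entity_chars, sz$n_entity_words, c(2L, 4L))
    marker_words <- make_words(marker_chars, sz$n_marker_words, c(2L, 2L))
    filler_words <- make_words(filler_chars, sz$n_filler_words, c(1L, 2L))

    ## one two-character connector word per relation (plus Other)
    n_conn_words <- sz$n_relations + 1L
    stopifnot(n_conn_chars >= 2L)
    conn_words <- character(0)
    guard <- 0L
    while (length(conn_words) < n_conn_words && guard < 1000L) {
      guard <- guard + 1L
      w <- paste(sample(conn_chars, 2L, replace = TRUE), collapse = "")
      if (!w %in% conn_words) conn_words <- c(conn_words, w)
    }

    rel <- data.frame(
      id = seq_len(sz$n_relations + 1L),
      name_zh = conn_words,
      name_en = c(paste0("relation-", seq_len(sz$n_relations)), "Other"),
      abbrev = c(paste0("R", seq_len(sz$n_relations)), "O"),
      stringsAsFactors = FALSE
    )
    schema <- new_relation_schema(rel)

    lexicon <- data.frame(
      word = c(entity_words, marker_words, filler_words, conn_words),
      type = rep(c("ENT", "MARK", "FILL", "CONN"),
                 c(length(entity_words), length(marker_words),
                   length(filler_words), length(conn_words))),
      stringsAsFactors = FALSE
    )

    structure(list(alphabet = alphabet, roles = roles,
                   radical_table = radical_table(mapping),
                   lexicon = lexicon, schema = schema,
                   connectors = stats::setNames(conn_words, rel$abbrev),
                   seed = seed, sizes = sz),
              class = "toy_language")
  })
}

#' Corpus generation settings
#'
#' @param n_sentences number of sentences.
#' @param relations_per_sentence probability weights over 1..5 gold
#'   (useful) triples per sentence; default uniform over 1..3.
#' @param noise_triple_prob probability that a sentence additionally
#'   carries one distractor clause whose triple is flagged Noise.
#' @param share_subject_prob probability that, in a sentence with >= 2
#'   relations, two relations share one subject (overlapping triples).
#' @param length_range admissible sentence length in characters.
#' @param seed integer seed.
#' @return a `gen_config` list.
#' @export
gen_config <- function(n_sentences, relations_per_sentence = c(1, 1, 1, 0, 0),
                       noise_triple_prob = 0.3, share_subject_prob = 0.25,
                       length_range = c(10L, 60L), seed = 1L) {
  stopifnot(n_sentences >= 0, length(relations_per_sentence) == 5,
            all(relations_per_sentence >= 0), sum(relations_per_sentence) > 0,
            noise_triple_prob >= 0, noise_triple_prob <= 1)
  structure(list(n_sentences = as.integer(n_sentences),
                 relations_per_sentence = relations_per_sentence,
                 noise_triple_prob = noise_triple_prob,
                 share_subject_prob = share_subject_prob,
                 length_range = as.integer(length_range),
                 seed = as.integer(seed)),
            class = "gen_config")
}

lex_words <- function(lang, type) lang$lexicon$word[lang$lexicon$type == type]

## Build one sentence; returns an annotated_sentence or NULL when the
## draw violates the length bounds (caller retries).
gen_sentence <- function(lang, cfg, id) {
  rels_all <- relation_abbrevs(lang$schema, include_other = FALSE)
  n_rel <- sample.int(5L, 1L, prob = cfg$relations_per_sentence)
  n_rel <- min(n_rel, length(rels_all))
  rels <- sample(rels_all, n_rel)
  ent <- lex_words(lang, "ENT")
  mark <- lex_words(lang, "MARK")
  fill <- lex_words(lang, "FILL")

  ## clause plans: lists of (words, triple specs relative to clause)
  clauses <- list()
  i <- 1L
  while (i <= n_rel) {
    share <- (i < n_rel) && stats::runif(1) < cfg$share_subject_prob
    subj <- sample(ent, 1L)
    if (share) {
      obj1 <- sample(setdiff(ent, subj), 1L)
      obj2 <- sample(setdiff(ent, c(subj, obj1)), 1L)
      clauses[[length(clauses) + 1L]] <- list(
        words = c(subj, lang$connectors[[rels[i]]], obj1,
                  lang$connectors[[rels[i + 1L]]], obj2),
        entity_idx = c(1L, 3L, 5L),
        relevance = "Food",
        triples = list(list(s = 1L, r = rels[i], o = 3L),
                       list(s = 1L, r = rels[i + 1L], o = 5L)))
      i <- i + 2L
    } else {
      obj <- sample(setdiff(ent, subj), 1L)
      clauses[[length(clauses) + 1L]] <- list(
        words = c(subj, lang$connectors[[rels[i]]], obj),
        entity_idx = c(1L, 3L),
        relevance = "Food",
        triples = list(list(s = 1L, r = rels[i], o = 3L)))
      i <- i + 1L
    }
  }
  if (stats::runif(1) < cfg$noise_triple_prob) {
    ## distractor clause: ordinary entities, flagged irrelevant only by
    ## the background-marker word that introduces the clause
    nsubj <- sample(ent, 1L)
    nobj <- sample(setdiff(ent, nsubj), 1L)
    nrel <- sample(rels_all, 1L)
    noise_clause <- list(words = c(sample(mark, 1L), nsubj,
                                   lang$connectors[[nrel]], nobj),
                         entity_idx = c(2L, 4L), relevance = "Noise",
                         triples = list(list(s = 2L, r = nrel, o = 4L)))
    pos <- sample.int(length(clauses) + 1L, 1L)
    clauses <- append(clauses, list(noise_clause), after = pos - 1L)
  }

  ## interleave filler runs: 0-2 words at the edges, 1-3 between clauses.
  ## The clause plan is fixed; only filler words are trimmed or padded to
  ## respect the length window, so the relations-per-sentence
  ## distribution is never biased by length rejection.
  pieces <- list()
  add_filler <- function(lo, hi) {
    k <- sample(lo:hi, 1L)
    pieces[[length(pieces) + 1L]] <<- list(words = if (k > 0) {
      sample(fill, k, replace = TRUE)
    } else character(0), clause = NULL)
  }
  add_filler(0L, 2L)
  for (ci in seq_along(clauses)) {
    pieces[[length(pieces) + 1L]] <- list(words = clauses[[ci]]$words, clause = ci)
    if (ci < length(clauses)) add_filler(1L, 3L)
  }
  add_filler(0L, 2L)

  total_len <- function() sum(nchar(unlist(lapply(pieces, `[[`, "words"))))
  filler_idx <- which(vapply(pieces, function(p) is.null(p$clause), logical(1)))
  ## trim: drop filler words, longest runs first, until the cap fits
  guard <- 0L
  while (total_len() > cfg$length_range[2] && guard < 100L) {
    guard <- guard + 1L
    sizes <- vapply(filler_idx, function(i) length(pieces[[i]]$words), integer(1))
    if (all(sizes == 0L)) break
    i <- filler_idx[which.max(sizes)]
    pieces[[i]]$words <- pieces[[i]]$words[-length(pieces[[i]]$words)]
  }
  ## pad: append filler words at the end until the floor is met
  while (total_len() < cfg$length_range[1]) {
    i <- filler_idx[length(filler_idx)]
    pieces[[i]]$words <- c(pieces[[i]]$words, sample(fill, 1L))
  }

  ## lay out characters and record spans
  offset <- 0L
  triples <- list()
  for (p in pieces) {
    if (length(p$words) == 0L) next
    word_starts <- offset + c(0L, cumsum(nchar(p$words)))[seq_along(p$words)]
    word_ends <- word_starts + nchar(p$words)
    if (!is.null(p$clause)) {
      cl <- clauses[[p$clause]]
      for (tsp in cl$triples) {
        triples[[length(triples) + 1L]] <- triple(
          subj = c(word_starts[tsp$s], word_ends[tsp$s]),
          rel = tsp$r,
          obj = c(word_starts[tsp$o], word_ends[tsp$o]),
          subj_rel = cl$relevance, obj_rel = cl$relevance)
      }
    }
    offset <- word_ends[length(word_ends)]
  }
  text <- paste(unlist(lapply(pieces, `[[`, "words")), collapse = "")
  if (nchar(text) < cfg$length_range[1] || nchar(text) > cfg$length_range[2]) {
    return(NULL)
  }
  annotated_sentence(id, text, triples)
}

#' Generate a synthetic annotated corpus
#'
#' Each sentence carries `N` useful triples (N drawn from
#' `cfg$relations_per_sentence`, relations distinct within a sentence)
#' plus, with probability `cfg$noise_triple_prob`, one distractor clause
#' flagged Noise.  Deterministic given `cfg$seed`; every generated
#' sentence passes the corpus validators and every entity span's text is
#' a lexicon word.
#'
#' @param lang a [make_toy_language()] result.
#' @param cfg a [gen_config()].
#' @return list of [annotated_sentence()] objects.
#' @export
generate_corpus <- function(lang, cfg) {
  stopifnot(inherits(lang, "toy_language"), inherits(cfg, "gen_config"))
  with_seed(cfg$seed, {
    out <- vector("list", cfg$n_sentences)
    for (i in seq_len(cfg$n_sentences)) {
      s <- NULL
      guard <- 0L
      while (is.null(s)) {
        guard <- guard + 1L
        if (guard > 200L) stop_bad("sentence generation exhausted length budget")
        s <- gen_sentence(lang, cfg, sprintf("s%05d", i))
      }
      out[[i]] <- s
    }
    out
  })
}

#' Summary statistics of an annotated corpus
#'
#' @param corpus list of annotated sentences.
#' @return a `corpus_stats` list: `n_sentences`, `n_triples`,
#'   `by_relation` (triple counts per relation abbrev), `by_n` (sentence
#'   counts per number of useful triples), `noise_fraction` (share of
#'   triples flagged Noise) and `noise_sentence_fraction` (share of
#'   sentences carrying at least one Noise triple).
#' @export
corpus_stats <- function(corpus) {
  by_relation <- integer(0)
  by_n <- integer(0)
  n_triples <- 0L
  n_noise <- 0L
  n_noise_sent <- 0L
  for (s in corpus) {
    n_useful <- 0L
    any_noise <- FALSE
    for (tr in s$triples) {
      n_triples <- n_triples + 1L
      by_relation[tr$rel] <- (if (is.na(by_relation[tr$rel])) 0L else by_relation[tr$rel]) + 1L
      if (tr$useful) n_useful <- n_useful + 1L else {
        n_noise <- n_noise + 1L
        any_noise <- TRUE
      }
    }
    if (any_noise) n_noise_sent <- n_noise_sent + 1L
    key <- as.character(n_useful)
    by_n[key] <- (if (is.na(by_n[key])) 0L else by_n[key]) + 1L
  }
  structure(list(n_sentences = length(corpus), n_triples = n_triples,
                 by_relation = by_relation, by_n = by_n,
                 noise_fraction = if (n_triples > 0) n_noise / n_triples else 0,
                 noise_sentence_fraction = if (length(corpus) > 0) {
                   n_noise_sent / length(corpus)
                 } else 0),
            class = "corpus_stats")
}
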