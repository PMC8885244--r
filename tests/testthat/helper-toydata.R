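# Shared fixtures, built in code.

toy_lang <- function(seed = 101L) make_toy_language(seed = seed)

tiny_corpus <- function(n = 5, seed = 3L, lang = toy_lang()) {
  generate_corpus(lang, gen_config(n, seed = seed))
}

## a tiny hand-made sentence: "AABccDD" style with one triple
hand_sentence <- function() {
  annotated_sentence(
    id = "hand-1",
    text = "食物含有纤维质量好",
    triples = list(
      triple(c(0L, 2L), "CO", c(4L, 6L))
    )
  )
}

tiny_encoder <- function(tokens = c("一", "二", "三", "四"), dim = 8L,
                         layers = 1L, seed = 5L) {
  build_encoder(encoder_config(make_vocab(tokens), dim = dim, layers = layers,
                               seed = seed))
}

## brute-force path enumeration oracle for linear-chain CRFs
crf_brute <- function(emissions, crf) {
  K <- crf$tag_count
  m <- nrow(emissions)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), m)))
  scores <- apply(paths, 1, function(p) {
    relcascade:::crf_path_score(emissions, p, crf)
  })
  list(logZ = relcascade:::logsumexp(scores),
       best = paths[which.max(scores), ],
       paths = paths, scores = scores)
}

triple_keys <- function(triples) {
  sort(vapply(triples, function(tr) {
    sprintf("%d-%d|%s|%d-%d", tr$subj$start, tr$subj$end, tr$rel,
            tr$obj$start, tr$obj$end)
  }, character(1)))
}
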