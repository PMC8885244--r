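test_that("toy languages are deterministic and cover the radical alphabet", {
  l1 <- make_toy_language(seed = 7)
  l2 <- make_toy_language(seed = 7)
  expect_identical(l1$radical_table$mapping, l2$radical_table$mapping)
  expect_identical(l1$lexicon, l2$lexicon)
  l3 <- make_toy_language(seed = 8)
  expect_false(identical(l1$lexicon, l3$lexicon))

  l40 <- make_toy_language(seed = 3, sizes = list(n_chars = 40, n_radicals = 8))
  expect_length(l40$alphabet, 40)
  mapped <- l40$radical_table$mapping[l40$alphabet]
  expect_false(anyNA(mapped))                       # every character mapped
  expect_length(unique(unname(mapped)), 8)          # exactly 8 radicals used
  ## pigeonhole: some radical covers at least ceil(40/8) = 5 characters
  expect_gte(max(table(mapped)), 5)
  expect_error(make_toy_language(seed = 1, sizes = list(n_chars = 4, n_radicals = 8)),
               "smaller than")
})

test_that("generated corpora are valid, deterministic, and respect configured sizes", {
  lang <- toy_lang()
  expect_length(generate_corpus(lang, gen_config(0, seed = 1)), 0)
  c1 <- generate_corpus(lang, gen_config(25, seed = 5))
  c2 <- generate_corpus(lang, gen_config(25, seed = 5))
  expect_identical(lapply(c1, `[[`, "text"), lapply(c2, `[[`, "text"))
  lens <- vapply(c1, function(s) nchar(s$text), integer(1))
  expect_true(all(lens >= 10 & lens <= 60))
  lex <- lang$lexicon$word
  for (s in c1) {
    validate_sentence <- relcascade:::validate_sentence
    expect_silent(validate_sentence(s, lang$schema))
    for (tr in s$triples) {
      ## every entity span's text is a lexicon word
      expect_true(substr(s$text, tr$subj$start + 1, tr$subj$end) %in% lex)
      expect_true(substr(s$text, tr$obj$start + 1, tr$obj$end) %in% lex)
      ## relevance flags are consistent with usefulness
      expect_identical(tr$useful,
                       tr$subj$relevance == "Food" && tr$obj$relevance == "Food")
    }
    ## BIO tagging must be expressible (no partial overlaps)
    expect_error(suppressMessages(encode_tags(s)), NA)
  }
})

test_that("relation-count distribution and noise rate match the configuration", {
  lang <- toy_lang()
  corp <- generate_corpus(lang, gen_config(2000, relations_per_sentence = c(1, 1, 1, 0, 0),
                                           noise_triple_prob = 0.3, seed = 17))
  st <- corpus_stats(corp)
  ## uniform over {1,2,3}: each within 3 sigma of 2000/3
  n <- 2000; p <- 1 / 3
  sigma <- sqrt(n * p * (1 - p))
  for (k in c("1", "2", "3")) {
    expect_lt(abs(st$by_n[[k]] - n * p), 3 * sigma)
  }
  ## Bernoulli noise-sentence rate within 3 sigma of 0.3
  sigma_noise <- sqrt(n * 0.3 * 0.7) / n
  expect_lt(abs(st$noise_sentence_fraction - 0.3), 3 * sigma_noise)
})

test_that("corpus statistics are internally consistent and additive", {
  lang <- toy_lang()
  st0 <- corpus_stats(list())
  expect_equal(st0$n_triples, 0L)
  expect_equal(st0$noise_fraction, 0)
  a <- generate_corpus(lang, gen_config(15, seed = 23))
  b <- generate_corpus(lang, gen_config(10, seed = 29))
  sa <- corpus_stats(a); sb <- corpus_stats(b); sab <- corpus_stats(c(a, b))
  expect_equal(sab$n_triples, sa$n_triples + sb$n_triples)
  expect_equal(sum(sab$by_relation), sab$n_triples)
  expect_equal(sum(sab$by_n), sab$n_sentences)
  for (r in names(sab$by_relation)) {
    expect_equal(sab$by_relation[[r]],
                 (if (r %in% names(sa$by_relation)) sa$by_relation[[r]] else 0L) +
                   (if (r %in% names(sb$by_relation)) sb$by_relation[[r]] else 0L))
  }
  one <- corpus_stats(list(annotated_sentence("x", "甲乙丙丁", list(
    triple(c(0, 2), "CO", c(2, 4)), triple(c(2, 4), "IS", c(0, 2))))))
  expect_equal(one$n_triples, 2L)
})
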