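test_that("subject scores are position-wise sigmoids of a linear map", {
  H <- matrix(rnorm(12), 4, 3)
  p0 <- list(W = matrix(0, 3, 2), b = c(0, 0))
  s <- subject_scores(H, p0)
  expect_equal(s$head, rep(0.5, 4))
  expect_equal(s$tail, rep(0.5, 4))
  pb <- list(W = matrix(0, 3, 2), b = c(2, -1))
  s2 <- subject_scores(H, pb)
  expect_equal(s2$head, rep(plogis(2), 4))
  expect_equal(s2$tail, rep(plogis(-1), 4))
  ## monotone in the logit
  p1 <- list(W = matrix(c(1, 0, 0, 0, 0, 0), 3, 2), b = c(0, 0))
  H2 <- H; H2[1, 1] <- H2[1, 1] + 1
  expect_gt(subject_scores(H2, p1)$head[1], subject_scores(H, p1)$head[1])
})

test_that("span decoding uses strict thresholds and nearest-tail pairing", {
  expect_equal(decode_spans(c(0.9, 0.1, 0.1), c(0.1, 0.1, 0.8), 0.5),
               list(c(0L, 3L)))
  expect_equal(decode_spans(c(0.4, 0.4), c(0.4, 0.4), 0.5), list())
  ## two heads, two tails, nearest pairing
  expect_equal(decode_spans(c(0.9, 0.1, 0.9, 0.1), c(0.1, 0.9, 0.1, 0.9), 0.5),
               list(c(0L, 2L), c(2L, 4L)))
  ## unpaired start (no tail at or after it) is dropped
  expect_equal(decode_spans(c(0.1, 0.9), c(0.9, 0.1), 0.5), list())
  ## boundary: probability equal to tau does not fire
  expect_equal(decode_spans(c(0.5, 0.5), c(0.5, 0.5), 0.5), list())
  ## raising tau never increases the number of spans
  withr::with_seed(3, {
    for (i in 1:50) {
      h <- runif(8); t <- runif(8)
      n <- vapply(c(0.2, 0.5, 0.8), function(tau) length(decode_spans(h, t, tau)),
                  numeric(1))
      expect_true(all(diff(n) <= 0))
    }
  })
})

test_that("subject conditioning adds the span summary to every position", {
  H <- matrix(c(1, 1, 3, 3, 10, 10), 3, 2, byrow = TRUE)
  out <- condition_subject(H, c(0L, 2L))$vectors       # mean of rows 1:2 = (2,2)
  expect_equal(out, H + matrix(2, 3, 2))
  out_head <- condition_subject(H, c(0L, 2L), pool = "head")$vectors
  expect_equal(out_head, H + matrix(c(1, 1), 3, 2, byrow = TRUE))
  ## single-character subject adds that row
  out1 <- condition_subject(H, c(2L, 3L))$vectors
  expect_equal(out1, H + matrix(c(10, 10), 3, 2, byrow = TRUE))
  ## zero summary leaves H unchanged
  H0 <- rbind(c(0, 0), c(5, 5))
  expect_equal(condition_subject(H0, c(0L, 1L))$vectors, H0)
  expect_error(condition_subject(H, c(2L, 5L)), "invalid subject span")
})

test_that("object scores have one head/tail row per relation, independently parameterised", {
  H <- matrix(rnorm(20), 5, 4)
  rels <- c("R1", "R2", "R3")
  p <- list(W = matrix(0, 4, 6), b = numeric(6), rels = rels)
  sc <- object_scores(H, p)
  expect_equal(dim(sc$head), c(3L, 5L))
  expect_equal(rownames(sc$head), rels)
  expect_true(all(sc$head == 0.5) && all(sc$tail == 0.5))
  ## perturbing relation 2's parameters leaves other rows unchanged
  p2 <- p; p2$W[, 3] <- rnorm(4); p2$b[4] <- 1
  sc2 <- object_scores(H, p2)
  expect_identical(sc$head[c(1, 3), ], sc2$head[c(1, 3), ])
  expect_identical(sc$tail[c(1, 3), ], sc2$tail[c(1, 3), ])
  expect_false(identical(sc$head[2, ], sc2$head[2, ]))
})

test_that("gold-score oracle decoding recovers exactly the gold triples", {
  lang <- toy_lang()
  corp <- generate_corpus(lang, gen_config(200, noise_triple_prob = 0.3, seed = 61))
  om <- gold_score_model(lang$schema)
  for (s in corp) {
    got <- extract_triples(s, om)
    expect_identical(triple_keys(got), triple_keys(s$triples))
  }
})

test_that("the worked example decodes four triples, two after the gold noise filter", {
  s <- example_sentence_food_safety()
  sch <- load_schema()
  all4 <- extract_triples(s, gold_score_model(sch))
  expect_length(all4, 4)
  expect_identical(triple_keys(all4), triple_keys(s$triples))
  kept <- extract_triples(s, gold_score_model(sch, extractor_config()))
  expect_length(kept, 2)
  expect_identical(triple_keys(kept),
                   triple_keys(Filter(function(tr) tr$useful, s$triples)))
  expect_setequal(vapply(kept, `[[`, character(1), "rel"), c("CO", "IS"))
})

test_that("an untrained all-zero tagger decodes nothing at tau = 0.5", {
  lang <- toy_lang()
  corp <- generate_corpus(lang, gen_config(3, seed = 71))
  cfg <- extractor_config(dim_char = 6, dim_radical = 4, dim_word = 4,
                          enc_layers_char = 0, enc_layers_radical = 0,
                          enc_layers_word = 0, seed = 1)
  model <- relcascade:::init_extractor_model(lang$schema, cfg, lang$radical_table,
                                             lang$lexicon$word, corp)
  model$params$sub$W[] <- 0; model$params$sub$b[] <- 0
  model$params$obj$W[] <- 0; model$params$obj$b[] <- 0
  expect_length(extract_triples(corp[[1]], model, mask_source = "gold"), 0)
})

test_that("training loss honours its analytic anchors", {
  lang <- toy_lang()
  corp <- generate_corpus(lang, gen_config(4, seed = 81))
  cfg <- extractor_config(dim_char = 6, dim_radical = 4, dim_word = 4,
                          enc_layers_char = 0, enc_layers_radical = 0,
                          enc_layers_word = 0, pos_weight = 1, seed = 2)
  model <- relcascade:::init_extractor_model(lang$schema, cfg, lang$radical_table,
                                             lang$lexicon$word, corp)
  ## all probabilities 0.5 -> loss is exactly log 2
  model$params$sub$W[] <- 0; model$params$sub$b[] <- 0
  model$params$obj$W[] <- 0; model$params$obj$b[] <- 0
  for (p in c("enc_c", "enc_r", "enc_w")) model$params[[p]]$emb[] <- 0
  withr::with_seed(1, l <- training_loss(corp, model))
  expect_equal(l, log(2), tolerance = 1e-9)
  ## the same anchor holds under positive-class weighting
  model$cfg$pos_weight <- 10
  withr::with_seed(1, expect_equal(training_loss(corp, model), log(2), tolerance = 1e-9))
  ## single-position BCE contribution: gold 1, p = 0.25 -> -log 0.25
  expect_equal(relcascade:::bce_loss(0.25, 1), -log(0.25), tolerance = 1e-9)
  ## near-perfect probabilities -> vanishing loss
  expect_lt(relcascade:::bce_loss(c(1 - 1e-7, 1e-7), c(1, 0)), 1e-5)
})

test_that("extractor training is deterministic given the seed and logs losses", {
  lang <- toy_lang()
  corp <- generate_corpus(lang, gen_config(10, seed = 91))
  cfg <- extractor_config(dim_char = 8, dim_radical = 4, dim_word = 4,
                          enc_layers_char = 1, enc_layers_radical = 0,
                          enc_layers_word = 0, epochs = 2, seed = 7)
  m1 <- train_extractor(corp, lang$schema, cfg, lang$radical_table, lang$lexicon$word)
  m2 <- train_extractor(corp, lang$schema, cfg, lang$radical_table, lang$lexicon$word)
  expect_length(m1$loss_log, 2)
  expect_identical(m1$loss_log, m2$loss_log)
  expect_identical(m1$params, m2$params)
  expect_error(train_extractor(list(), lang$schema, cfg), "empty corpus")
})
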