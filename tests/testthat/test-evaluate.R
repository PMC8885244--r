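test_that("triple matching is exact on span boundaries and relation", {
  g <- list(triple(c(0, 2), "CO", c(3, 5)),
            triple(c(0, 2), "IS", c(6, 8)),
            triple(c(9, 11), "CO", c(3, 5)),
            triple(c(12, 14), "EF", c(3, 5)))
  p_exact <- g[1:3]
  expect_equal(match_triples(p_exact, g), list(tp = 3L, fp = 0L, fn = 1L))
  expect_equal(match_triples(list(), g), list(tp = 0L, fp = 0L, fn = 4L))
  ## 2 correct + 1 spurious against 4 gold
  p_mix <- list(g[[1]], g[[2]], triple(c(0, 3), "CO", c(3, 5)))
  expect_equal(match_triples(p_mix, g), list(tp = 2L, fp = 1L, fn = 2L))
  ## a near miss (offset by one) is not a match
  expect_equal(match_triples(list(triple(c(0, 2), "CO", c(3, 6))), g[1])$tp, 0L)
})

test_that("precision/recall/F1 arithmetic and degenerate cases", {
  m <- prf(list(tp = 2, fp = 1, fn = 2))
  expect_equal(m$precision, 2 / 3, tolerance = 1e-12)
  expect_equal(m$recall, 1 / 2, tolerance = 1e-12)
  expect_equal(m$f1, 4 / 7, tolerance = 1e-12)
  perfect <- prf(list(tp = 5, fp = 0, fn = 0))
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))
  w <- capture_warnings(z <- prf(list(tp = 0, fp = 0, fn = 0)))
  expect_length(w, 2)   # degenerate precision and recall both warn
  expect_equal(c(z$precision, z$recall, z$f1), c(0, 0, 0))
  ## F1 lies between P and R whenever both are positive
  withr::with_seed(4, {
    for (i in 1:30) {
      ct <- list(tp = sample(1:20, 1), fp = sample(0:20, 1), fn = sample(0:20, 1))
      m <- prf(ct)
      expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
      expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
    }
  })
})

test_that("t-based confidence intervals match the closed form", {
  ci <- confidence_interval(c(90, 91, 92), 0.95)
  expect_equal(ci$mean, 91)
  expect_equal(ci$halfwidth, qt(0.975, 2) * sd(c(90, 91, 92)) / sqrt(3))
  expect_equal(ci$halfwidth, 2.484, tolerance = 1e-3)
  expect_equal(confidence_interval(c(5, 5, 5, 5))$halfwidth, 0)
  expect_error(confidence_interval(42), "at least 2")
})

test_that("corpus evaluation aggregates micro counts and stratifies by N", {
  lang <- toy_lang()
  corp <- generate_corpus(lang, gen_config(40, seed = 41))
  om <- gold_score_model(lang$schema, extractor_config())  # gold noise filter on
  pred <- extract_corpus(corp, om)
  ev <- suppressMessages(evaluate_extraction(pred, corp, by_n = TRUE))
  expect_equal(ev$precision, rep(1, nrow(ev)))
  expect_equal(ev$recall, rep(1, nrow(ev)))
  expect_equal(ev$f1, rep(1, nrow(ev)))
  ## strata partition the overall counts
  expect_equal(sum(ev$tp[-1]), ev$tp[1])
  expect_equal(sum(ev$n_sentences[-1]), ev$n_sentences[1])
  ## dropping predictions for one sentence shows up as false negatives
  pred2 <- pred
  pred2[[corp[[1]]$id]] <- list()
  ev2 <- evaluate_extraction(pred2, corp)
  n1 <- length(Filter(function(tr) tr$useful, corp[[1]]$triples))
  expect_equal(ev2$fn[1], n1)
  expect_lt(ev2$recall[1], 1)
  ## missing ids are an error
  expect_error(evaluate_extraction(pred[-1], corp), "missing predictions")
})

test_that("empty strata are omitted with a message", {
  lang <- toy_lang()
  corp <- generate_corpus(lang, gen_config(5, relations_per_sentence = c(1, 0, 0, 0, 0),
                                           seed = 47))
  om <- gold_score_model(lang$schema, extractor_config())
  pred <- extract_corpus(corp, om)
  expect_message(ev <- evaluate_extraction(pred, corp, by_n = TRUE), "omitted")
  expect_equal(ev$stratum, c("overall", "N=1"))
})

test_that("file-based evaluation aligns sentences by id", {
  lang <- toy_lang()
  corp <- generate_corpus(lang, gen_config(8, seed = 53))
  om <- gold_score_model(lang$schema, extractor_config())
  pred_sentences <- lapply(corp, function(s) {
    annotated_sentence(s$id, s$text, extract_triples(s, om))
  })
  fg <- withr::local_tempfile(fileext = ".jsonl")
  fp <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corp, fg)
  write_corpus(pred_sentences, fp)
  ev <- evaluate_files(fp, fg, lang$schema)
  expect_equal(ev$f1[1], 1)
  write_corpus(pred_sentences[-1], fp)
  expect_error(evaluate_files(fp, fg, lang$schema), "ids differ")
})
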