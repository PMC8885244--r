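test_that("entity spans become prefix-B/prefix-I runs with O elsewhere", {
  s <- example_sentence_food_safety()
  tags <- encode_tags(s)
  expect_length(tags, nchar(s$text))
  ## distractor drug mention at the sentence start
  expect_equal(as.character(tags[1:6]),
               c("Noise-B", "Noise-I", "Noise-I", "Noise-I", "O", "O"))
  ## relevant mention of the same drug later in the sentence
  expect_equal(as.character(tags[33:36]),
               c("Food-B", "Food-I", "Food-I", "Food-I"))
  ## a sentence without triples is all O
  empty <- annotated_sentence("e", "恩诺沙星属于")
  expect_equal(as.character(encode_tags(empty)), rep("O", 6))
})

test_that("relevance conflicts resolve to Food and nesting keeps the outer span", {
  s <- annotated_sentence("c", "甲乙丙丁戊", list(
    triple(c(0, 2), "CO", c(3, 5), subj_rel = "Noise"),
    triple(c(3, 5), "IS", c(0, 2), subj_rel = "Food", obj_rel = "Food")
  ))
  expect_message(tags <- encode_tags(s), "conflict resolved to Food")
  expect_equal(as.character(tags), c("Food-B", "Food-I", "O", "Food-B", "Food-I"))

  nested <- annotated_sentence("n", "甲乙丙丁戊", list(
    triple(c(0, 4), "CO", c(4, 5)),
    triple(c(1, 3), "IS", c(4, 5))
  ))
  expect_message(tags2 <- encode_tags(nested), "nested")
  expect_equal(as.character(tags2),
               c("Food-B", "Food-I", "Food-I", "Food-I", "Food-B"))

  partial <- annotated_sentence("p", "甲乙丙丁戊", list(
    triple(c(0, 3), "CO", c(4, 5)),
    triple(c(2, 4), "IS", c(4, 5))
  ))
  expect_error(encode_tags(partial), "overlap")
})

test_that("decode_tags inverts encode_tags and repairs orphan I", {
  expect_equal(
    lapply(decode_tags(c("Food-B", "Food-I", "O")), function(x) c(x$start, x$end)),
    list(c(0L, 2L)))
  expect_length(decode_tags(c("O", "O", "O")), 0)
  expect_message(sp <- decode_tags(c("Food-I", "O")), "orphan")
  expect_equal(c(sp[[1]]$start, sp[[1]]$end, sp[[1]]$relevance), c("0", "1", "Food"))
  expect_error(decode_tags(c("Food-B", "X")), "unknown tags")
})

test_that("encode/decode round trip is the identity on non-overlapping span sets", {
  lang <- toy_lang()
  corp <- generate_corpus(lang, gen_config(40, seed = 21))
  for (s in corp) {
    tags <- encode_tags(s)
    got <- decode_tags(as.character(tags))
    want <- unique(unlist(lapply(s$triples, function(tr) {
      lapply(list(tr$subj, tr$obj), function(sp) {
        sprintf("%d-%d-%s", sp$start, sp$end, sp$relevance)
      })
    })))
    got_keys <- vapply(got, function(sp) sprintf("%d-%d-%s", sp$start, sp$end, sp$relevance),
                       character(1))
    expect_setequal(got_keys, want)
  }
})

test_that("position mask keeps Food always, zeroes Noise always, policy governs O", {
  tags <- c("Food-B", "Food-I", "O", "Noise-B", "Noise-I")
  expect_equal(position_mask(tags, "keep_outside"), c(1, 1, 1, 0, 0))
  expect_equal(position_mask(tags, "literal"), c(1, 1, 0, 0, 0))
  expect_equal(position_mask(rep("O", 4)), rep(1, 4))
  expect_equal(position_mask(rep("O", 4), "literal"), rep(0, 4))
})
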