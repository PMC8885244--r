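test_that("bundled schema has the twelve food-health relations in order", {
  sch <- load_schema()
  expect_s3_class(sch, "relation_schema")
  expect_equal(nrow(sch), 12L)
  expect_equal(sch$abbrev,
               c("CO", "AN", "BE", "IN", "EF", "NC", "IS", "DE", "CT", "FC",
                 "AR", "O"))
  expect_equal(sch$abbrev[1], "CO")
  expect_equal(sch$abbrev[12], "O")
  expect_equal(sch$name_en[12], "Other")
  expect_true(attr(sch, "includes_other"))
  expect_equal(relation_abbrevs(sch, include_other = FALSE), sch$abbrev[1:11])
})

test_that("schema loading validates structure", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"relations": [{"id": 1, "name_zh": "x", "name_en": "X", "abbrev": "XX"}]}', f)
  expect_equal(nrow(load_schema(f)), 1L)

  dup <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0('{"relations": [',
                    '{"id": 1, "name_zh": "a", "name_en": "A", "abbrev": "CO"},',
                    '{"id": 2, "name_zh": "b", "name_en": "B", "abbrev": "CO"}]}'), dup)
  expect_error(load_schema(dup), "duplicate")

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("not json {", bad)
  expect_error(load_schema(bad), "parse")
})

test_that("sentence and triple invariants are enforced", {
  expect_error(entity_span(3, 3), "start < end")
  expect_error(entity_span(-1, 2), "start < end")
  expect_error(entity_span(0, 2, "Maybe"), "relevance")
  tr <- triple(c(0, 2), "CO", c(3, 5), obj_rel = "Noise")
  expect_false(tr$useful)
  expect_true(triple(c(0, 2), "CO", c(3, 5))$useful)
  expect_error(annotated_sentence("x", ""), "non-empty")
  expect_error(
    annotated_sentence("x", "abc", list(triple(c(0, 2), "CO", c(2, 5)))),
    "out of bounds")
})

test_that("corpus serialisation round-trips byte-identically", {
  lang <- toy_lang()
  corp <- tiny_corpus(6, seed = 9, lang = lang)
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corp, f1)
  back <- read_corpus(f1, lang$schema)
  expect_length(back, 6)
  write_corpus(back, f2)
  expect_identical(readLines(f1, encoding = "UTF-8"),
                   readLines(f2, encoding = "UTF-8"))
  ## structural equality too
  for (i in seq_along(corp)) {
    expect_identical(corp[[i]]$text, back[[i]]$text)
    expect_identical(triple_keys(corp[[i]]$triples), triple_keys(back[[i]]$triples))
  }
})

test_that("corpus reading reports offending line and unknown relation", {
  sch <- load_schema()
  f <- withr::local_tempfile(fileext = ".jsonl")
  good <- '{"id":"a","text":"恩诺沙星","triples":[]}'
  bad_span <- '{"id":"b","text":"恩诺","triples":[{"subj":[0,5],"rel":"CO","obj":[0,1],"subj_rel":"Food","obj_rel":"Food"}]}'
  writeLines(c(good, bad_span), f)
  expect_error(read_corpus(f, sch), "line 2")
  bad_rel <- '{"id":"c","text":"恩诺沙星","triples":[{"subj":[0,2],"rel":"ZZ","obj":[2,4],"subj_rel":"Food","obj_rel":"Food"}]}'
  writeLines(c(good, bad_rel), f)
  expect_error(read_corpus(f, sch), "unknown relation")
  writeLines(good, f)
  expect_length(read_corpus(f, sch), 1)
})
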