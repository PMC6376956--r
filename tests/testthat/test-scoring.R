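test_that("tokenizer follows the documented dialect", {
  expect_equal(tokenize("I am always tired.")$total, 4L)
  expect_equal(tokenize("don't stop")$tokens, c("don't", "stop"))
  expect_equal(tokenize("")$total, 0L)
  expect_equal(tokenize("Well-known fact")$tokens,
               c("well", "known", "fact"))
  expect_equal(tokenize("I have 3 cats")$total, 4L)
  # sentence ids advance at terminators and newlines
  ts <- tokenize("one two. three\nfour")
  expect_equal(ts$sentence, c(1L, 1L, 2L, 3L))
  # unicode apostrophe is normalized
  expect_equal(tokenize("don’t")$tokens, "don't")
})

test_that("vectorized tokenization matches the scalar tokenizer", {
  texts <- c("Hello everyone. Not completely lost; almost\ncompletely done!",
             "", "one", "a. b. c.", "It's 2 a.m., don't ask")
  many <- absolex:::tokenize_many(texts)
  for (i in seq_along(texts)) {
    one <- tokenize(texts[i])
    expect_identical(many[[i]]$tokens, one$tokens)
    expect_identical(many[[i]]$sentence, one$sentence)
    expect_identical(many[[i]]$total, one$total)
  }
})

test_that("raw, fp and corrected indices match direct arithmetic", {
  lex <- tiny_lexicon()
  # 3 hits in 200 tokens -> 1.5
  toks <- c(rep("the", 197), "always", "nothing", "completely")
  ts <- structure(list(tokens = toks, sentence = rep(1L, 200), total = 200L),
                  class = "absolex_tokens")
  expect_equal(raw_index(ts, lex), 1.5)
  expect_equal(fp_index(ts, lex), 0)
  expect_equal(corrected_index(ts, lex), 1.5)
  expect_equal(raw_index(tokenize("no hits here at all"), lex), 0)
  expect_error(raw_index(tokenize(""), lex), "empty document")
})

test_that("false-positive phrases match by type, position and sentence", {
  lex <- tiny_lexicon()
  # negation and qualifier
  expect_equal(fp_index(tokenize("i am not completely sure"), lex), 20)
  expect_equal(fp_index(tokenize("it is almost completely done"), lex), 20)
  # salutation only when it starts within the first 3 tokens
  expect_equal(fp_index(tokenize("hello everyone i am here"), lex), 20)
  expect_equal(fp_index(tokenize("oh so hello everyone welcome"), lex), 20)
  expect_equal(fp_index(tokenize("so i said hello everyone later"), lex), 0)
  # negation must not straddle a sentence boundary
  expect_equal(fp_index(tokenize("it is not. completely done"), lex), 0)
  expect_equal(fp_index(tokenize("it is not\ncompletely done"), lex), 0)
  # corrected subtracts matches: "not always" has no phrase for "always"
  expect_equal(corrected_index(tokenize("not always"), lex), 50)
})

test_that("every planted negation cancels: corrected index is exactly zero", {
  lex <- lexicon("abs", "always",
                 data.frame(phrase = "not always", type = "negation"))
  doc <- paste(rep("not always", 50), collapse = " ")
  expect_equal(raw_index(tokenize(doc), lex), 50)
  expect_equal(corrected_index(tokenize(doc), lex), 0)
  # salutation at document start contributes zero after correction
  lex2 <- tiny_lexicon()
  doc2 <- paste("hello everyone", paste(rep("word", 48), collapse = " "))
  expect_equal(corrected_index(tokenize(doc2), lex2), 0)
})

test_that("indices equal the brute-force oracle on random fixtures", {
  lex <- tiny_lexicon()
  set.seed(20240101)
  for (rep in 1:50) {
    ts <- random_token_fixture(if (rep <= 25) 50L else 2000L, lex)
    expect_equal(raw_index(ts, lex),
                 100 * oracle_raw_count(ts$tokens, lex$words) / ts$total)
    expect_equal(fp_index(ts, lex),
                 100 * oracle_fp_count(ts$tokens, ts$sentence, lex) / ts$total)
  }
})

test_that("per-word indices are additive and consistent with the raw index", {
  ws <- c("always", "never")
  wi <- word_indices(tokenize("always always never"), ws)
  expect_equal(unname(wi), c(200 / 3, 100 / 3))
  expect_equal(word_indices(tokenize("always tired"), "nothing")[["nothing"]],
               0)
  lex <- tiny_lexicon()
  set.seed(7)
  ts <- random_token_fixture(500L, lex)
  expect_equal(sum(word_indices(ts, lex$words)), raw_index(ts, lex),
               tolerance = 1e-9)
})

test_that("indices are invariant to duplicating the document", {
  lex <- tiny_lexicon()
  doc <- "i am not completely sure. i always feel nothing is real."
  dup <- paste(doc, doc)
  for (f in list(raw_index, fp_index, corrected_index)) {
    expect_equal(f(tokenize(dup), lex), f(tokenize(doc), lex))
  }
  # the salutation rule is positional, so it is the one exception:
  # duplicating a document that opens with a salutation loses one fp match
  sdoc <- "hello everyone. i am not completely sure."
  sdup <- paste(sdoc, sdoc)
  expect_equal(fp_index(tokenize(sdup), lex),
               fp_index(tokenize(sdoc), lex) - 100 / tokenize(sdup)$total)
})

test_that("score_corpus is deterministic and propagates member structure", {
  cfg <- small_synth_config()
  gen <- generate_corpus(cfg)
  lexes <- list(cfg$lexicon, standin_nonabsolutist_lexicon())
  tab <- score_corpus(gen$tree, lexes)
  expect_s3_class(tab, "absolex_index_table")
  expect_equal(nrow(tab), nrow(gen$tree))
  expect_true(all(c("absolutist_raw", "absolutist_fp", "absolutist_corrected",
                    "nonabsolutist_raw") %in% names(tab)))
  # invariants: 0 <= fp <= raw <= 100, corrected = raw - fp
  expect_true(all(tab$absolutist_fp >= 0))
  expect_true(all(tab$absolutist_fp <= tab$absolutist_raw))
  expect_true(all(tab$absolutist_raw <= 100))
  expect_equal(tab$absolutist_corrected,
               tab$absolutist_raw - tab$absolutist_fp)
  expect_identical(tab, score_corpus(gen$tree, lexes))

  # word-index matrix rows sum to the lexicon's raw index
  wm <- word_index_matrix(gen$tree, cfg$lexicon$words)
  expect_equal(rowSums(as.matrix(wm[cfg$lexicon$words])),
               tab$absolutist_raw, tolerance = 1e-9,
               ignore_attr = TRUE)
})
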