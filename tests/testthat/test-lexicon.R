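test_that("lexicon files round-trip and invariants are enforced", {
  path <- withr::local_tempfile(fileext = ".lex")
  writeLines(c("# comment", "Always", "totally", "entire",
               "~not always\tnegation"), path)
  lex <- read_lexicon(path, category = "absolutist")
  expect_s3_class(lex, "absolex_lexicon")
  expect_setequal(lex$words, c("always", "totally", "entire"))
  expect_equal(nrow(lex$fp_phrases), 1L)
  expect_equal(lex$fp_phrases$word, "always")

  # round trip preserves content
  out <- withr::local_tempfile(fileext = ".lex")
  write_lexicon(lex, out)
  lex2 <- read_lexicon(out, name = lex$name, category = "absolutist")
  expect_equal(lex2$words, lex$words)
  expect_equal(lex2$fp_phrases$phrase, lex$fp_phrases$phrase)

  writeLines(c("# only a comment"), path)
  expect_error(read_lexicon(path), "empty lexicon")
  writeLines(c("always", "totally", "always"), path)
  expect_error(read_lexicon(path), "duplicate.*always")

  # a phrase must embed exactly one lexicon word
  expect_error(lexicon("x", c("always", "never"),
                       data.frame(phrase = "always never", type = "negation")),
               "exactly one lexicon word")
  expect_error(lexicon("x", "always",
                       data.frame(phrase = "so not", type = "negation")),
               "exactly one lexicon word")
  expect_error(lexicon("x", character()), "empty lexicon")
  expect_error(lexicon("x", c("a b", "c")), "single tokens")
})

test_that("the shipped lexicons load with the documented structure", {
  abs <- default_absolutist_lexicon()
  expect_length(abs$words, 19L)
  # the documented exemplars are all present
  expect_true(all(c("always", "totally", "entire", "completely", "nothing",
                    "everyone", "definitely") %in% abs$words))
  expect_setequal(abs$fp_phrases$type,
                  c("negation", "qualifier", "salutation"))
  non <- standin_nonabsolutist_lexicon()
  expect_length(non$words, 43L)
  expect_equal(sum(attr(non, "word_tags") == "extreme", na.rm = TRUE), 21L)
  expect_length(intersect(abs$words, non$words), 0L)
})

make_panel <- function(votes_by_judge) {
  # votes_by_judge: list(judge = c(item = "label1,label2", ...))
  rows <- do.call(rbind, lapply(names(votes_by_judge), function(j) {
    v <- votes_by_judge[[j]]
    data.frame(item = names(v), judge = j, labels = unname(v))
  }))
  judge_panel(rows)
}

test_that("majority vote finalizes categories and reassigns failed proposals", {
  items <- c("always", "anything", "need")
  judges <- paste0("j", 1:5)
  votes <- lapply(judges, function(j) {
    c(always = "absolute",
      anything = if (j %in% c("j1", "j2")) "absolute" else "nonabsolute",
      need = if (j == "j1") "absolute,extreme" else "nonabsolute")
  })
  names(votes) <- judges
  panel <- make_panel(votes)
  proposed <- c(always = "absolute", anything = "absolute", need = "absolute")
  res <- majority_categorize(panel, proposed)
  expect_equal(res$final$final_category,
               c("absolute", "nonabsolute", "nonabsolute"))
  expect_setequal(res$reassigned, c("anything", "need"))
  expect_length(res$unresolved, 0L)

  # strict majority: 2 absolute / 3 nonabsolute -> nonabsolute
  votes2 <- lapply(judges, function(j) {
    c(w = if (j %in% c("j1", "j2")) "absolute" else "nonabsolute")
  })
  names(votes2) <- judges
  res2 <- majority_categorize(make_panel(votes2), c(w = "nonabsolute"))
  expect_equal(res2$final$final_category, "nonabsolute")
  expect_length(res2$reassigned, 0L)
})

test_that("even-panel ties are flagged unresolved, not silently assigned", {
  votes <- list(j1 = c(w = "extreme"), j2 = c(w = "nonabsolute"))
  res <- majority_categorize(make_panel(votes), c(w = "nonabsolute"))
  expect_equal(res$unresolved, "w")
  expect_equal(res$final$final_category, "unresolved")
})

test_that("majority vote is invariant to judge order", {
  set.seed(42)
  items <- paste0("w", 1:12)
  judges <- paste0("j", 1:5)
  base <- do.call(rbind, lapply(judges, function(j) {
    data.frame(item = items, judge = j,
               labels = sample(c("absolute", "nonabsolute", "extreme",
                                 "absolute,extreme"), 12, replace = TRUE))
  }))
  proposed <- stats::setNames(sample(c("absolute", "nonabsolute"), 12,
                                     replace = TRUE), items)
  r1 <- majority_categorize(judge_panel(base), proposed)
  shuffled <- base[sample(nrow(base)), ]
  r2 <- majority_categorize(judge_panel(shuffled), proposed)
  expect_equal(r1$final[order(r1$final$item), ],
               r2$final[order(r2$final$item), ])
  expect_equal(r1$interjudge_agreement, r2$interjudge_agreement)
})

test_that("percentage agreement matches hand counts", {
  a <- stats::setNames(rep("absolute", 10), paste0("w", 1:10))
  expect_equal(agreement(a, a), 100)
  b <- a; b[] <- "nonabsolute"
  expect_equal(agreement(a, b), 0)
  # 65 items, 4 discordant: 61/65 = 93.846%
  a65 <- stats::setNames(rep("absolute", 65), paste0("w", 1:65))
  b65 <- a65
  b65[c(3, 17, 40, 64)] <- "nonabsolute"
  expect_equal(agreement(a65, b65), 100 * 61 / 65, tolerance = 1e-4)
  expect_error(agreement(a, b65), "identical item sets")
})

test_that("interjudge agreement equals the brute-force pairwise mean", {
  items <- paste0("w", 1:9)
  lab <- list(
    j1 = c("absolute", "absolute", "nonabsolute", "extreme", "absolute",
           "nonabsolute", "nonabsolute", "absolute", "extreme"),
    j2 = c("absolute", "nonabsolute", "nonabsolute", "extreme", "absolute",
           "absolute", "nonabsolute", "absolute", "nonabsolute"),
    j3 = c("nonabsolute", "absolute", "nonabsolute", "nonabsolute",
           "absolute", "nonabsolute", "extreme", "absolute", "extreme")
  )
  panel <- make_panel(lapply(lab, function(v) stats::setNames(v, items)))
  # brute force: enumerate the three pairs directly
  pct <- function(x, y) 100 * mean(x == y)
  expected <- mean(c(pct(lab$j1, lab$j2), pct(lab$j1, lab$j3),
                     pct(lab$j2, lab$j3)))
  expect_equal(interjudge_agreement(panel), expected)

  # identical judges -> 100; fully discordant pair -> 0
  same <- make_panel(list(j1 = c(w1 = "absolute", w2 = "extreme"),
                          j2 = c(w1 = "absolute", w2 = "extreme")))
  expect_equal(interjudge_agreement(same), 100)
  diff2 <- make_panel(list(j1 = c(w1 = "absolute", w2 = "absolute"),
                           j2 = c(w1 = "nonabsolute", w2 = "extreme")))
  expect_equal(interjudge_agreement(diff2), 0)
  single <- make_panel(list(j1 = c(w1 = "absolute")))
  expect_error(interjudge_agreement(single), ">= 2 judges")
})

test_that("judge vote TSV loads into a panel", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("item\tjudge\tlabels",
               "always\tj1\tabsolute",
               "always\tj2\tabsolute, extreme",
               "very\tj1\textreme",
               "very\tj2\tnonabsolute"), path)
  panel <- read_judge_votes(path)
  expect_equal(nrow(panel), 4L)
  expect_equal(panel$labels[[2]], c("absolute", "extreme"))
  expect_error(judge_panel(data.frame(item = "w", judge = "j",
                                      labels = "bogus")),
               "unknown vote label")
})
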