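# Independent brute-force oracles, deliberately coded differently from the
# package implementation.

# raw hits: explicit linear scan
oracle_raw_count <- function(tokens, words) {
  hits <- 0L
  for (t in tokens) if (t %in% words) hits <- hits + 1L
  hits
}

# false-positive phrase matches: left-to-right greedy scan, longest phrase
# first at each position, jumping past consumed tokens; negation/qualifier
# must sit inside one sentence, salutations must start in the first
# `window` tokens of the document
oracle_fp_count <- function(tokens, sentence, lex, window = 3L) {
  phr <- lex$fp_phrases
  if (nrow(phr) == 0L) return(0L)
  ord <- order(-lengths(phr$tokens))
  n <- length(tokens)
  count <- 0L
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (k in ord) {
      p <- phr$tokens[[k]]
      L <- length(p)
      if (i + L - 1L > n) next
      if (!all(tokens[i:(i + L - 1L)] == p)) next
      if (phr$type[k] == "salutation") {
        if (i > window) next
      } else {
        if (sentence[i] != sentence[i + L - 1L]) next
      }
      count <- count + 1L
      i <- i + L
      matched <- TRUE
      break
    }
    if (!matched) i <- i + 1L
  }
  count
}

# closed-form weighted one-way ANOVA
oracle_weighted_anova_F <- function(y, g, w) {
  g <- factor(g)
  ybar <- sum(w * y) / sum(w)
  gm <- tapply(w * y, g, sum) / tapply(w, g, sum)
  ssb <- sum(tapply(w, g, sum) * (gm - ybar)^2)
  ssw <- sum(w * (y - gm[g])^2)
  k <- nlevels(g)
  n <- length(y)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# random token fixture over a vocabulary salted with lexicon words and
# phrase fragments, so raw hits, partial phrases and full phrases all occur
random_token_fixture <- function(n, lex, extra = c("the", "a", "of", "to",
                                                   "feel", "think", "sad")) {
  vocab <- c(lex$words, unlist(lex$fp_phrases$tokens), extra)
  toks <- sample(vocab, n, replace = TRUE)
  sent <- cumsum(stats::runif(n) < 0.08) + 1L
  sent <- match(sent, unique(sent))
  structure(list(tokens = toks, sentence = sent, total = n),
            class = "absolex_tokens")
}

# rebuild text from a token stream so package scoring can run on it:
# sentence breaks become periods
fixture_text <- function(ts) {
  out <- ts$tokens
  brk <- which(diff(ts$sentence) > 0)
  out[brk] <- paste0(out[brk], ".")
  paste(out, collapse = " ")
}
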