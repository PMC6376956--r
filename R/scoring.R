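#' Tokenize a document
#'
#' Lowercases and splits on whitespace and punctuation, keeping internal
#' apostrophes so contractions ("don't") are single tokens. Numerals count
#' as tokens. Sentence boundaries (used to constrain phrase matching) are
#' taken at `.`, `!`, `?`, `;` and newlines; hyphens split tokens.
#'
#' @param text A length-1 character string (UTF-8).
#' @return Object of class `absolex_tokens`: list with `tokens` (lowercase
#'   character vector), `sentence` (integer sentence id per token), and
#'   `total` (token count).
#' @export
#' @examples
#' tokenize("I am always tired.")$total
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(structure(list(tokens = character(), sentence = integer(),
                          total = 0L), class = "absolex_tokens"))
  }
  text <- stringi::stri_trans_tolower(text)
  text <- stringi::stri_replace_all_fixed(text, "’", "'")
  sents <- stringi::stri_split_regex(text, "[.!?;\n]+")[[1]]
  toks <- stringi::stri_extract_all_regex(
    sents, "[\\p{L}\\p{N}]+(?:'[\\p{L}\\p{N}]+)*", omit_no_match = TRUE)
  n <- lengths(toks)
  sent <- rep.int(seq_along(sents), n)
  structure(
    list(tokens = unlist(toks, use.names = FALSE),
         sentence = match(sent, unique(sent)),
         total = sum(n)),
    class = "absolex_tokens"
  )
}

#' @export
print.absolex_tokens <- function(x, ...) {
  cat(sprintf("<token stream: %d tokens, %d sentences>\n", x$total,
              if (x$total) max(x$sentence) else 0L))
  invisible(x)
}

as_tokens <- function(x) {
  if (inherits(x, "absolex_tokens")) x else tokenize(x)
}

# Vectorized tokenization of many documents in one stringi pass: tokens and
# sentence-break marks are extracted together, and sentence ids recovered
# from the break positions. Produces the same streams as tokenize() on each
# document.
tokenize_many <- function(texts) {
  texts <- stringi::stri_trans_tolower(texts)
  texts <- stringi::stri_replace_all_fixed(texts, "’", "'")
  ex <- stringi::stri_extract_all_regex(
    texts, "[\\p{L}\\p{N}]+(?:'[\\p{L}\\p{N}]+)*|[.!?;\n]+",
    omit_no_match = TRUE)
  lapply(ex, function(v) {
    is_break <- stringi::stri_detect_regex(v, "^[.!?;\n]")
    sent <- cumsum(c(TRUE, is_break[-length(v)]))[!is_break]
    tk <- v[!is_break]
    structure(list(tokens = tk,
                   sentence = if (length(tk)) match(sent, unique(sent))
                              else integer(),
                   total = length(tk)),
              class = "absolex_tokens")
  })
}

#' Raw lexicon index
#'
#' Prevalence of a lexicon in a document as a percentage of the total number
#' of tokens: `100 * hits / total`.
#'
#' @param tokens An `absolex_tokens` object or a character string.
#' @param lex An `absolex_lexicon`.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' raw_index(tokenize("always never maybe sometimes"),
#'           lexicon("abs", c("always", "never")))
raw_index <- function(tokens, lex) {
  tokens <- as_tokens(tokens)
  stopifnot(inherits(lex, "absolex_lexicon"))
  if (tokens$total == 0L) stop("empty document")
  100 * sum(tokens$tokens %in% lex$words) / tokens$total
}

# Locate false-positive phrase matches: contiguous token subsequences,
# leftmost and non-overlapping, with each lexicon-word token consumed by at
# most one match. Negation/qualifier phrases must lie within a single
# sentence; salutation phrases only match when they start within the first
# `salutation_window` tokens of the document.
fp_match_positions <- function(tokens, lex, salutation_window = 3L) {
  tt <- tokens$tokens
  n <- tokens$total
  cand <- list()
  for (i in seq_len(nrow(lex$fp_phrases))) {
    p <- lex$fp_phrases$tokens[[i]]
    type <- lex$fp_phrases$type[i]
    L <- length(p)
    starts <- which(tt == p[1L])
    starts <- starts[starts + L - 1L <= n]
    if (type == "salutation") starts <- starts[starts <= salutation_window]
    for (s in starts) {
      span <- s:(s + L - 1L)
      if (!all(tt[span] == p)) next
      if (type != "salutation" &&
          length(unique(tokens$sentence[span])) != 1L) next
      cand[[length(cand) + 1L]] <- list(start = s, span = span, phrase = i)
    }
  }
  if (length(cand) == 0L) return(cand)
  # leftmost-first, ties broken toward the longer phrase
  ord <- order(vapply(cand, `[[`, 0L, "start"),
               -lengths(lapply(cand, `[[`, "span")))
  consumed <- logical(n)
  keep <- list()
  for (k in ord) {
    span <- cand[[k]]$span
    if (any(consumed[span])) next
    consumed[span] <- TRUE
    keep[[length(keep) + 1L]] <- cand[[k]]
  }
  keep
}

#' False-positive index
#'
#' Percentage of tokens accounted for by false-positive phrase matches of a
#' lexicon: `100 * matches / total`. Each match embeds exactly one lexicon
#' word, and matches are non-overlapping, so the false-positive index never
#' exceeds the raw index; subtracting it yields the corrected index on the
#' same per-token scale.
#'
#' @inheritParams raw_index
#' @param salutation_window Salutation phrases only match when they start
#'   within this many tokens of the document start (default 3).
#' @return Percentage in `[0, 100]`.
#' @export
fp_index <- function(tokens, lex, salutation_window = 3L) {
  tokens <- as_tokens(tokens)
  stopifnot(inherits(lex, "absolex_lexicon"))
  if (tokens$total == 0L) stop("empty document")
  if (nrow(lex$fp_phrases) == 0L) return(0)
  100 * length(fp_match_positions(tokens, lex, salutation_window)) /
    tokens$total
}

#' False-positive corrected index
#'
#' The raw index minus the false-positive index; nonnegative by the lexicon
#' invariant that every phrase embeds exactly one lexicon word.
#'
#' @inheritParams fp_index
#' @return Percentage in `[0, 100]`.
#' @export
corrected_index <- function(tokens, lex, salutation_window = 3L) {
  tokens <- as_tokens(tokens)
  raw_index(tokens, lex) - fp_index(tokens, lex, salutation_window)
}

#' Per-word indices
#'
#' Percentage prevalence of each individual word; the values sum to the raw
#' index of the word set.
#'
#' @inheritParams raw_index
#' @param words Character vector of words.
#' @return Named numeric vector of percentages.
#' @export
word_indices <- function(tokens, words) {
  tokens <- as_tokens(tokens)
  if (tokens$total == 0L) stop("empty document")
  words <- tolower(words)
  counts <- table(factor(tokens$tokens[tokens$tokens %in% words],
                         levels = words))
  out <- 100 * as.numeric(counts) / tokens$total
  names(out) <- words
  out
}

#' Score every member document of a corpus against a set of lexicons
#'
#' @param tree An `absolex_corpus` (see [load_corpus()] or
#'   [generate_corpus()]).
#' @param lexicons An `absolex_lexicon` or list of them.
#' @param salutation_window Passed to [fp_index()].
#' @return An index table: a tibble of class `absolex_index_table` with one
#'   row per member document, columns `group`, `forum`, `member`,
#'   `word_count`, and for each lexicon `<name>_raw`, `<name>_fp`,
#'   `<name>_corrected` (percentages).
#' @export
score_corpus <- function(tree, lexicons, salutation_window = 3L) {
  stopifnot(inherits(tree, "absolex_corpus"))
  if (inherits(lexicons, "absolex_lexicon")) lexicons <- list(lexicons)
  stopifnot(length(lexicons) > 0L,
            all(vapply(lexicons, inherits, logical(1), "absolex_lexicon")))
  if (nrow(tree) == 0L) stop("empty corpus")
  out <- tibble::tibble(group = tree$group, forum = tree$forum,
                        member = tree$member, word_count = tree$word_count)
  streams <- tokenize_many(tree$text)
  empty <- vapply(streams, function(s) s$total == 0L, logical(1))
  if (any(empty)) {
    stop("empty document for member(s): ",
         paste(tree$member[empty], collapse = ", "))
  }
  for (lex in lexicons) {
    raw <- vapply(streams, raw_index, numeric(1), lex = lex)
    fp <- vapply(streams, fp_index, numeric(1), lex = lex,
                 salutation_window = salutation_window)
    out[[paste0(lex$name, "_raw")]] <- raw
    out[[paste0(lex$name, "_fp")]] <- fp
    out[[paste0(lex$name, "_corrected")]] <- raw - fp
  }
  class(out) <- c("absolex_index_table", class(out))
  out
}

#' Per-word index matrix for a corpus
#'
#' One row per member document, one column per word, cells the percentage
#' prevalence of that word in the member's document. Row sums over a
#' lexicon's words equal the lexicon's raw index.
#'
#' @param tree An `absolex_corpus`.
#' @param words Character vector of words (for instance the union of an
#'   absolutist and a nonabsolutist lexicon).
#' @return Tibble with id columns `group`, `forum`, `member` followed by one
#'   numeric column per word.
#' @export
word_index_matrix <- function(tree, words) {
  stopifnot(inherits(tree, "absolex_corpus"))
  words <- tolower(words)
  rows <- lapply(tokenize_many(tree$text), word_indices, words = words)
  m <- do.call(rbind, rows)
  out <- tibble::tibble(group = tree$group, forum = tree$forum,
                        member = tree$member)
  for (j in seq_along(words)) out[[words[j]]] <- m[, j]
  out
}

#' Write an index table (or any tibble) as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
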