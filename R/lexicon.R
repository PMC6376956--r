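#' Construct a lexicon
#'
#' A lexicon is a named closed vocabulary: a set of lowercase single-token
#' entries, optionally accompanied by multiword false-positive phrase
#' patterns. Each phrase contains exactly one lexicon word, so subtracting
#' phrase matches from raw word matches can never drive an index negative.
#' Phrases are tagged by the mechanism that makes the embedded word a false
#' positive: a preceding negation ("not completely"), a preceding qualifier
#' ("almost completely"), or a salutation ("hello everyone"), which is
#' positional and only matched near the start of a document.
#'
#' @param name Label for the lexicon (used as a column prefix in index
#'   tables).
#' @param words Character vector of single-token entries; lowercased and
#'   deduplication is an error, not silent.
#' @param fp_phrases Optional data frame with columns `phrase` (a multiword
#'   string) and `type` (one of `"negation"`, `"qualifier"`, `"salutation"`),
#'   or `NULL`.
#' @param category One of `"absolutist"`, `"nonabsolutist"`, `"other"`.
#' @return An object of class `absolex_lexicon`: a list with fields `name`,
#'   `category`, `words`, and `fp_phrases` (a tibble with columns `phrase`,
#'   `type`, `tokens` (list of token vectors), and `word`, the embedded
#'   lexicon word).
#' @export
#' @examples
#' lex <- lexicon("abs", c("always", "completely"),
#'                fp_phrases = data.frame(phrase = "not completely",
#'                                        type = "negation"))
#' lex$words
lexicon <- function(name, words, fp_phrases = NULL, category = "other") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  category <- match.arg(category, c("absolutist", "nonabsolutist", "other"))
  if (length(words) == 0L) stop("empty lexicon: '", name, "' has no entries")
  words <- tolower(trimws(words))
  if (any(!nzchar(words))) stop("empty lexicon entry in '", name, "'")
  dup <- unique(words[duplicated(words)])
  if (length(dup) > 0L) {
    stop("duplicate lexicon entr", if (length(dup) > 1L) "ies: " else "y: ",
         paste(dQuote(dup, FALSE), collapse = ", "))
  }
  if (any(stringi::stri_detect_regex(words, "\\s"))) {
    bad <- words[stringi::stri_detect_regex(words, "\\s")]
    stop("lexicon entries must be single tokens: ",
         paste(dQuote(bad, FALSE), collapse = ", "))
  }
  fp <- validate_fp_phrases(fp_phrases, words)
  structure(
    list(name = name, category = category, words = words, fp_phrases = fp),
    class = "absolex_lexicon"
  )
}

validate_fp_phrases <- function(fp_phrases, words) {
  if (is.null(fp_phrases) || NROW(fp_phrases) == 0L) {
    return(tibble::tibble(phrase = character(), type = character(),
                          tokens = list(), word = character()))
  }
  fp_phrases <- as.data.frame(fp_phrases)
  stopifnot(all(c("phrase", "type") %in% names(fp_phrases)))
  type <- match.arg(tolower(fp_phrases$type),
                    c("negation", "qualifier", "salutation"),
                    several.ok = TRUE)
  phrase <- tolower(trimws(fp_phrases$phrase))
  toks <- lapply(phrase, function(p) tokenize(p)$tokens)
  n_lex <- vapply(toks, function(tk) sum(tk %in% words), integer(1))
  if (any(n_lex != 1L)) {
    bad <- phrase[n_lex != 1L]
    stop("false-positive phrase must contain exactly one lexicon word: ",
         paste(dQuote(bad, FALSE), collapse = ", "))
  }
  if (any(lengths(toks) < 2L)) {
    stop("false-positive phrases must be multiword: ",
         paste(dQuote(phrase[lengths(toks) < 2L], FALSE), collapse = ", "))
  }
  word <- vapply(seq_along(toks),
                 function(i) toks[[i]][toks[[i]] %in% words][1L],
                 character(1))
  tibble::tibble(phrase = phrase, type = type, tokens = toks, word = word)
}

#' @export
print.absolex_lexicon <- function(x, ...) {
  cat(sprintf("<lexicon '%s' (%s): %d words, %d false-positive phrases>\n",
              x$name, x$category, length(x$words), nrow(x$fp_phrases)))
  invisible(x)
}

#' Read a lexicon from a plain-text file
#'
#' File format: UTF-8 text, one word per line. Lines beginning with `#` are
#' comments; lines beginning with `~` declare a false-positive phrase and
#' carry a tab-separated tag, e.g. `~not completely<TAB>negation`.
#'
#' @param path Path to the lexicon file.
#' @param name Lexicon label; defaults to the file name without extension.
#' @param category Lexicon category, see [lexicon()].
#' @return An `absolex_lexicon`.
#' @export
read_lexicon <- function(path, name = NULL,
                         category = c("other", "absolutist", "nonabsolutist")) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  category <- match.arg(category)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  is_fp <- startsWith(lines, "~")
  words <- lines[!is_fp]
  # word lines may carry a tab-separated tag (e.g. "very<TAB>extreme"); only
  # the first field is the entry
  tags <- rep(NA_character_, length(words))
  has_tab <- grepl("\t", words, fixed = TRUE)
  tags[has_tab] <- sub("^[^\t]*\t", "", words[has_tab])
  words <- sub("\t.*$", "", words)
  if (length(words) == 0L) stop("empty lexicon: ", path)
  fp <- NULL
  if (any(is_fp)) {
    parts <- strsplit(sub("^~", "", lines[is_fp]), "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      stop("malformed false-positive phrase line in ", path,
           " (expected '~<phrase>\\t<tag>')")
    }
    fp <- data.frame(phrase = vapply(parts, `[[`, "", 1L),
                     type = vapply(parts, `[[`, "", 2L))
  }
  lex <- lexicon(name, words, fp_phrases = fp, category = category)
  attr(lex, "word_tags") <- tags
  lex
}

#' Write a lexicon to its plain-text file format
#'
#' @param lex An `absolex_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "absolex_lexicon"))
  lines <- c(sprintf("# lexicon: %s (%s)", lex$name, lex$category),
             lex$words,
             sprintf("~%s\t%s", lex$fp_phrases$phrase, lex$fp_phrases$type))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Default absolutist lexicon
#'
#' The 19-word absolutist dictionary (words denoting totality of magnitude
#' or probability without nuance, validated by an expert judge panel),
#' together with the three archetypal false-positive phrase patterns:
#' a negation before the absolutist word ("not completely"), a qualifier
#' before it ("almost completely"), and a salutation ("hello everyone").
#' User lexicons can extend the phrase inventory via [read_lexicon()].
#'
#' @return An `absolex_lexicon` with category `"absolutist"`.
#' @export
default_absolutist_lexicon <- function() {
  read_lexicon(system.file("extdata", "absolutist.lex", package = "absolex"),
               name = "absolutist", category = "absolutist")
}

#' Stand-in nonabsolutist lexicon
#'
#' A synthetic stand-in for a nonabsolutist (nuance) dictionary: the
#' published word list is not redistributable here, so this lexicon contains
#' the documented exemplars (rather, somewhat, likely, very, really,
#' anything, need, needed) padded with generic nuance and intensifier
#' vocabulary to 43 entries, 21 of which are tagged "extreme". Suitable for
#' tests and examples, not for reproducing published dictionary scores.
#'
#' @return An `absolex_lexicon` with category `"nonabsolutist"`.
#' @export
standin_nonabsolutist_lexicon <- function() {
  read_lexicon(system.file("extdata", "nonabsolutist_standin.lex",
                           package = "absolex"),
               name = "nonabsolutist", category = "nonabsolutist")
}

# ---- judge-panel vote aggregation ------------------------------------------

#' Construct a judge panel
#'
#' Holds the categorization votes of independent judges over candidate
#' dictionary words. Judges may place a word in more than one category, so
#' each vote is a set of labels drawn from `{absolute, nonabsolute, extreme}`.
#'
#' @param votes Data frame with columns `item`, `judge`, `labels`
#'   (comma-separated label string, or a list column of character vectors).
#' @return Object of class `absolex_judge_panel`.
#' @export
judge_panel <- function(votes) {
  votes <- as.data.frame(votes)
  stopifnot(all(c("item", "judge", "labels") %in% names(votes)))
  lab <- votes$labels
  if (!is.list(lab)) lab <- strsplit(as.character(lab), ",[ ]*")
  lab <- lapply(lab, function(x) {
    x <- tolower(trimws(x))
    x <- x[nzchar(x)]
    bad <- setdiff(x, c("absolute", "nonabsolute", "extreme"))
    if (length(bad) > 0L) stop("unknown vote label: ",
                               paste(bad, collapse = ", "))
    unique(x)
  })
  if (any(lengths(lab) == 0L)) stop("every (item, judge) vote needs >= 1 label")
  if (length(unique(votes$judge)) < 1L) stop("judge count must be >= 1")
  key <- paste(votes$item, votes$judge, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (item, judge) vote")
  structure(
    tibble::tibble(item = as.character(votes$item),
                   judge = as.character(votes$judge), labels = lab),
    class = c("absolex_judge_panel", class(tibble::tibble()))
  )
}

#' Read judge votes from a TSV file
#'
#' Columns: `item`, `judge`, `labels` (comma-separated).
#'
#' @param path TSV path.
#' @return An `absolex_judge_panel`.
#' @export
read_judge_votes <- function(path) {
  judge_panel(utils::read.delim(path, stringsAsFactors = FALSE))
}

# Primary category of a multi-label vote. The final dictionary decision is
# binary (absolute vs not), so "absolute" outranks "extreme" outranks
# "nonabsolute" when a judge ticked several boxes.
primary_label <- function(labels) {
  for (l in c("absolute", "extreme", "nonabsolute")) {
    if (l %in% labels) return(l)
  }
  stop("empty vote")
}

#' Finalize dictionary membership by majority decision
#'
#' Each item's final category is the label endorsed by a strict majority of
#' judges (multi-label votes count toward every label they contain, with the
#' membership question resolved in the precedence absolute > extreme >
#' nonabsolute). Items that were proposed as absolute but fail to obtain an
#' absolute majority are reassigned to nonabsolute. Items with no strict
#' majority for any label and no applicable fallback are flagged
#' `"unresolved"` and should be excluded from the final lexicon (this can
#' occur with an even judge panel).
#'
#' @param panel An `absolex_judge_panel`.
#' @param proposed Named character vector or list mapping item to its
#'   proposed category (`"absolute"`, `"nonabsolute"`, or `"extreme"`).
#' @return Object of class `absolex_validation`: list with `final` (tibble
#'   of item, proposed, final_category, n_judges), `reassigned` (items whose
#'   final category differs from the proposal), `unresolved`,
#'   `author_judge_agreement` (named percentage per judge, on the binary
#'   absolute/nonabsolute split), and `interjudge_agreement` (percentage).
#' @export
majority_categorize <- function(panel, proposed) {
  stopifnot(inherits(panel, "absolex_judge_panel"))
  proposed <- unlist(proposed)
  items <- unique(panel$item)
  if (!all(items %in% names(proposed))) {
    stop("proposed categories missing for: ",
         paste(setdiff(items, names(proposed)), collapse = ", "))
  }
  final <- character(length(items))
  for (i in seq_along(items)) {
    v <- panel$labels[panel$item == items[i]]
    n <- length(v)
    counts <- vapply(c("absolute", "extreme", "nonabsolute"),
                     function(l) sum(vapply(v, function(s) l %in% s,
                                            logical(1))),
                     integer(1))
    majority <- names(counts)[counts > n / 2]
    if ("absolute" %in% majority) {
      final[i] <- "absolute"
    } else if (length(majority) > 0L) {
      # precedence among the remaining labels
      final[i] <- intersect(c("extreme", "nonabsolute"), majority)[1L]
    } else if (identical(unname(proposed[items[i]]), "absolute")) {
      # proposed absolute but lacking an absolute majority: reassigned
      final[i] <- "nonabsolute"
    } else {
      final[i] <- "unresolved"
    }
  }
  reassigned <- items[final != unname(proposed[items]) & final != "unresolved"]
  unresolved <- items[final == "unresolved"]
  structure(
    list(
      final = tibble::tibble(item = items,
                             proposed = unname(proposed[items]),
                             final_category = final),
      reassigned = reassigned,
      unresolved = unresolved,
      author_judge_agreement = author_judge_agreement(panel, proposed),
      interjudge_agreement = interjudge_agreement(panel)
    ),
    class = "absolex_validation"
  )
}

# binary collapse used for author-vs-judge agreement: absolute vs not
binary_label <- function(l) if (l == "absolute") "absolute" else "nonabsolute"

author_judge_agreement <- function(panel, proposed) {
  proposed <- unlist(proposed)
  judges <- unique(panel$judge)
  out <- vapply(judges, function(j) {
    sub <- panel[panel$judge == j, ]
    jp <- vapply(sub$labels, function(s) binary_label(primary_label(s)),
                 character(1))
    pp <- vapply(unname(proposed[sub$item]), binary_label, character(1))
    100 * mean(jp == pp)
  }, numeric(1))
  names(out) <- judges
  out
}

#' Percentage agreement between two categorizations
#'
#' @param a,b Named character vectors mapping the same items to categories.
#' @return Percentage of items with equal category, in `[0, 100]`.
#' @export
#' @examples
#' agreement(c(x = "absolute", y = "nonabsolute"),
#'           c(x = "absolute", y = "absolute"))
agreement <- function(a, b) {
  a <- unlist(a); b <- unlist(b)
  if (!setequal(names(a), names(b)) || length(a) != length(b)) {
    stop("agreement() requires identical item sets")
  }
  if (length(a) == 0L) stop("agreement() on empty item set")
  100 * mean(unname(a[names(a)]) == unname(b[names(a)]))
}

#' Mean pairwise interjudge agreement
#'
#' Agreement between each pair of judges on the primary category of each
#' item (multi-label votes are collapsed by the precedence absolute >
#' extreme > nonabsolute), averaged over all judge pairs.
#'
#' @param panel An `absolex_judge_panel` with at least two judges.
#' @return Percentage in `[0, 100]`.
#' @export
interjudge_agreement <- function(panel) {
  stopifnot(inherits(panel, "absolex_judge_panel"))
  judges <- unique(panel$judge)
  if (length(judges) < 2L) stop("interjudge agreement needs >= 2 judges")
  items <- unique(panel$item)
  # items x judges matrix of primary categories
  m <- matrix(NA_character_, length(items), length(judges),
              dimnames = list(items, judges))
  for (k in seq_len(nrow(panel))) {
    m[panel$item[k], panel$judge[k]] <- primary_label(panel$labels[[k]])
  }
  pairs <- utils::combn(length(judges), 2)
  mean(apply(pairs, 2, function(p) 100 * mean(m[, p[1]] == m[, p[2]],
                                              na.rm = TRUE)))
}

#' @export
print.absolex_validation <- function(x, ...) {
  cat(sprintf(
    "<lexicon validation: %d items, %d reassigned, %d unresolved>\n",
    nrow(x$final), length(x$reassigned), length(x$unresolved)))
  cat(sprintf("  interjudge agreement: %.1f%%\n", x$interjudge_agreement))
  cat(sprintf("  author-judge agreement: %s\n",
              paste(sprintf("%s %.0f%%", names(x$author_judge_agreement),
                            x$author_judge_agreement), collapse = ", ")))
  invisible(x)
}
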