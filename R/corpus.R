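#' Apply post-selection rules
#'
#' Retains posts that (a) contain at least `min_words` tokens, (b) are first
#' posts (thread-opening, not replies), and (c) are continuous prose (not
#' lists or poems). The two flags are caller-supplied metadata and default to
#' `TRUE`; word counts are computed with [tokenize()] when absent. Order is
#' preserved and the operation is idempotent.
#'
#' @param posts Data frame with columns `author`, `text`, and optionally
#'   `word_count`, `is_first_post`, `is_prose`.
#' @param min_words Minimum token count for inclusion (default 100).
#' @return The selected rows, with `word_count` filled in.
#' @export
select_posts <- function(posts, min_words = 100L) {
  posts <- tibble::as_tibble(posts)
  stopifnot(all(c("author", "text") %in% names(posts)))
  if (!"word_count" %in% names(posts)) {
    posts$word_count <- vapply(posts$text,
                               function(t) tokenize(t)$total, integer(1),
                               USE.NAMES = FALSE)
  }
  if (!"is_first_post" %in% names(posts)) posts$is_first_post <- TRUE
  if (!"is_prose" %in% names(posts)) posts$is_prose <- TRUE
  posts[posts$word_count >= min_words & posts$is_first_post & posts$is_prose, ]
}

#' Combine each member's posts into a single document
#'
#' One document per distinct author; texts are joined with a single newline
#' (which the tokenizer treats as a sentence boundary, so no false-positive
#' phrase can span a post join), and word counts are additive.
#'
#' @param posts Data frame of already-selected posts (see [select_posts()]).
#' @return Tibble with columns `member`, `text`, `word_count`, one row per
#'   author, in order of first appearance.
#' @export
aggregate_members <- function(posts) {
  posts <- tibble::as_tibble(posts)
  stopifnot(all(c("author", "text") %in% names(posts)))
  if (!"word_count" %in% names(posts)) {
    posts$word_count <- vapply(posts$text,
                               function(t) tokenize(t)$total, integer(1),
                               USE.NAMES = FALSE)
  }
  authors <- unique(posts$author)
  idx <- split(seq_len(nrow(posts)), factor(posts$author, levels = authors))
  tibble::tibble(
    member = authors,
    text = vapply(idx, function(i) paste(posts$text[i], collapse = "\n"),
                  character(1), USE.NAMES = FALSE),
    word_count = vapply(idx, function(i) sum(posts$word_count[i]),
                        numeric(1), USE.NAMES = FALSE)
  )
}

new_corpus <- function(group, forum, member, text, word_count = NULL) {
  if (is.null(word_count)) {
    word_count <- vapply(text, function(t) tokenize(t)$total, integer(1),
                         USE.NAMES = FALSE)
  }
  tree <- tibble::tibble(group = as.character(group),
                         forum = as.character(forum),
                         member = as.character(member),
                         text = text, word_count = as.numeric(word_count))
  key <- paste(tree$group, tree$forum, tree$member, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate member id within a forum: ",
         tree$member[duplicated(key)][1L])
  }
  class(tree) <- c("absolex_corpus", class(tree))
  tree
}

#' @export
print.absolex_corpus <- function(x, ...) {
  cat(sprintf("<corpus: %d groups, %d forums, %d member documents, %s words>\n",
              length(unique(x$group)),
              length(unique(paste(x$group, x$forum))),
              nrow(x), format(sum(x$word_count), big.mark = ",")))
  invisible(x)
}

#' Load a nested corpus from a directory tree
#'
#' Canonical layout: `root/<group>/<forum>/<member>.txt`, one UTF-8 plain
#' text document per member. An optional per-forum sidecar `posts.tsv`
#' (columns `file`, `is_first_post`, `is_prose`) marks files to exclude;
#' bare files default to first-post prose, since archived corpora are
#' typically already post-selection. A warning is raised for any forum whose
#' total word count falls below `floor_words` (forums below that floor were
#' excluded from the original design), and a message reports forums short of
#' the `target_words` collection target.
#'
#' @param root Corpus root directory.
#' @param floor_words Per-forum word-count floor (default 10000).
#' @param target_words Per-forum collection target (default 30000).
#' @return An `absolex_corpus` tibble (`group`, `forum`, `member`, `text`,
#'   `word_count`) with attribute `forum_totals`, a tibble of per-forum word
#'   totals.
#' @export
load_corpus <- function(root, floor_words = 10000, target_words = 30000) {
  if (!dir.exists(root)) stop("corpus root not found: ", root)
  groups <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(groups) == 0L) stop("no group directories under ", root)
  rows <- list()
  for (g in groups) {
    forums <- sort(list.dirs(file.path(root, g), recursive = FALSE,
                             full.names = FALSE))
    if (length(forums) == 0L) stop("group '", g, "' has no forum directories")
    for (f in forums) {
      fdir <- file.path(root, g, f)
      files <- sort(list.files(fdir, pattern = "\\.txt$"))
      sidecar <- file.path(fdir, "posts.tsv")
      if (file.exists(sidecar)) {
        meta <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
        drop <- meta$file[!(as.logical(meta$is_first_post) &
                              as.logical(meta$is_prose))]
        files <- setdiff(files, drop)
      }
      if (length(files) == 0L) stop("empty forum directory: ", fdir)
      texts <- vapply(file.path(fdir, files), function(p) {
        raw <- readBin(p, "raw", file.size(p))
        txt <- rawToChar(raw)
        if (!all(validUTF8(txt))) stop("undecodable (non-UTF-8) file: ", p)
        # trailing newline is a file-format artifact, not document content
        sub("[\r\n]+$", "", enc2utf8(txt))
      }, character(1), USE.NAMES = FALSE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = g, forum = f, member = sub("\\.txt$", "", files),
        text = texts)
    }
  }
  tree <- do.call(rbind, rows)
  tree <- new_corpus(tree$group, tree$forum, tree$member, tree$text)
  totals <- forum_totals(tree)
  attr(tree, "forum_totals") <- totals
  low <- totals[totals$total_words < floor_words, ]
  if (nrow(low) > 0L) {
    warning("forum(s) below the ", floor_words, "-word floor: ",
            paste(sprintf("%s/%s (%d)", low$group, low$forum,
                          low$total_words), collapse = ", "))
  }
  short <- totals[totals$total_words < target_words, ]
  if (nrow(short) > 0L) {
    message(nrow(short), " forum(s) short of the ", target_words,
            "-word collection target")
  }
  tree
}

#' Per-forum word totals
#'
#' @param tree An `absolex_corpus`.
#' @return Tibble with `group`, `forum`, `n_members`, `total_words`.
#' @export
forum_totals <- function(tree) {
  stopifnot(inherits(tree, "absolex_corpus"))
  key <- paste(tree$group, tree$forum, sep = "\r")
  idx <- split(seq_len(nrow(tree)), key)
  tibble::tibble(
    group = vapply(idx, function(i) tree$group[i[1]], character(1),
                   USE.NAMES = FALSE),
    forum = vapply(idx, function(i) tree$forum[i[1]], character(1),
                   USE.NAMES = FALSE),
    n_members = lengths(idx),
    total_words = vapply(idx, function(i) sum(tree$word_count[i]), numeric(1),
                         USE.NAMES = FALSE)
  )
}

#' Corpus manifest
#'
#' @param tree An `absolex_corpus`.
#' @return Tibble with `group`, `forum`, `member`, `word_count`.
#' @export
corpus_manifest <- function(tree) {
  stopifnot(inherits(tree, "absolex_corpus"))
  tibble::tibble(group = tree$group, forum = tree$forum, member = tree$member,
                 word_count = tree$word_count)
}

#' Write a corpus to the canonical directory layout
#'
#' @param tree An `absolex_corpus`.
#' @param root Output directory (created if needed).
#' @return `root`, invisibly.
#' @export
write_corpus <- function(tree, root) {
  stopifnot(inherits(tree, "absolex_corpus"))
  for (i in seq_len(nrow(tree))) {
    d <- file.path(root, tree$group[i], tree$forum[i])
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
    writeLines(tree$text[i], file.path(d, paste0(tree$member[i], ".txt")),
               useBytes = TRUE)
  }
  invisible(root)
}
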