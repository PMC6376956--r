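# Small fixtures shared across test files; everything is built in code.

tiny_lexicon <- function() {
  lexicon("abs", c("always", "completely", "everyone", "nothing"),
          fp_phrases = data.frame(
            phrase = c("not completely", "almost completely",
                       "hello everyone"),
            type = c("negation", "qualifier", "salutation")),
          category = "absolutist")
}

# index table built directly (no text): group/forum structure plus an
# outcome column on the percentage scale
make_index_table <- function(groups, forums_per_group, members_per_forum,
                             outcome_fn, word_counts = 300, seed = 1) {
  set.seed(seed)
  rows <- expand.grid(member = seq_len(members_per_forum),
                      forum = seq_len(forums_per_group),
                      group = groups, stringsAsFactors = FALSE)
  n <- nrow(rows)
  tibble::tibble(
    group = rows$group,
    forum = paste0(rows$group, "_f", rows$forum),
    member = paste0("m", seq_len(n)),
    word_count = rep_len(word_counts, n),
    score = outcome_fn(n, rows$group, rows$forum)
  )
}

# tiny on-disk corpus: 2 groups x 2 forums x 3 members
write_tiny_corpus <- function(root, n_groups = 2, n_forums = 2,
                              n_members = 3, words = 120) {
  for (g in paste0("g", seq_len(n_groups))) {
    for (f in paste0("f", seq_len(n_forums))) {
      dir.create(file.path(root, g, f), recursive = TRUE,
                 showWarnings = FALSE)
      for (m in paste0("m", seq_len(n_members))) {
        txt <- paste(rep(c("one", "two", "always", "three."), words / 4),
                     collapse = " ")
        writeLines(txt, file.path(root, g, f, paste0(m, ".txt")))
      }
    }
  }
  root
}

small_synth_config <- function(...) {
  args <- list(...)
  defaults <- list(
    groups = data.frame(name = c("a", "b"), mu = c(1.0, 1.5),
                        n_forums = 3L, members_per_forum = 15L),
    wordcount_meanlog = log(200), wordcount_sdlog = 0.3,
    seed = 11L
  )
  do.call(synth_config, utils::modifyList(defaults, args))
}
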