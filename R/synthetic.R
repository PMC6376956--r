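filler_vocabulary <- function() {
  path <- system.file("extdata", "filler_words.txt", package = "absolex")
  readLines(path, encoding = "UTF-8")
}

#' Configuration for the synthetic corpus generator
#'
#' Defines a nested members-within-forums-within-groups corpus with known
#' truth. Group means are target false-positive-corrected absolutist indices
#' in percent; forum and member effects are Gaussian on the log10(x+1)
#' transformed scale, so the default generator matches the assumptions of
#' [fit_mixed()] (`re_scale = "raw"` provides a misspecification toggle with
#' Gaussian effects on the raw percentage scale). Member word counts follow
#' a lognormal law truncated below at `wordcount_min`. A fraction `fp_rate`
#' of absolutist emissions is wrapped in a negation/qualifier false-positive
#' phrase, and each document opens with a salutation phrase with probability
#' `salutation_rate`. The defaults mirror the scale of the motivating forum
#' study: four to seven forums per group, about 100 members per forum,
#' roughly 300 words per member, and group means between 0.97% and 1.80%.
#'
#' @param groups Data frame with columns `name`, `mu` (target corrected
#'   index, percent), `n_forums`, `members_per_forum`.
#' @param sigma_forum,sigma_member Between-forum and between-member SDs on
#'   the transformed scale.
#' @param wordcount_meanlog,wordcount_sdlog,wordcount_min Lognormal word
#'   count law, truncated below.
#' @param fp_rate Fraction of absolutist emissions wrapped in a
#'   false-positive phrase.
#' @param salutation_rate Probability that a document opens with the
#'   lexicon's salutation phrase.
#' @param aux_lexicons Optional named list of auxiliary lexicons; each name
#'   must have an emission probability in `aux_rates`.
#' @param aux_rates Named numeric vector of per-token emission probabilities
#'   for the auxiliary lexicons.
#' @param sentence_len Sentence length in emission slots (a period is
#'   inserted after every `sentence_len` slots).
#' @param re_scale `"transformed"` (default) or `"raw"`.
#' @param lexicon The absolutist lexicon to emit from (default
#'   [default_absolutist_lexicon()]).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return Object of class `absolex_synth_config`.
#' @export
synth_config <- function(groups = NULL, sigma_forum = 0.05,
                         sigma_member = 0.18,
                         wordcount_meanlog = log(280), wordcount_sdlog = 0.4,
                         wordcount_min = 100L, fp_rate = 0.1,
                         salutation_rate = 0.1, aux_lexicons = list(),
                         aux_rates = numeric(), sentence_len = 15L,
                         re_scale = c("transformed", "raw"),
                         lexicon = default_absolutist_lexicon(),
                         seed = 20180105L) {
  if (is.null(groups)) {
    groups <- data.frame(
      name = c("control", "anxiety", "depression", "suicide"),
      mu = c(0.97, 1.45, 1.45, 1.80),
      n_forums = c(7L, 6L, 6L, 4L),
      members_per_forum = 100L
    )
  }
  groups <- as.data.frame(groups)
  stopifnot(all(c("name", "mu", "n_forums", "members_per_forum") %in%
                  names(groups)),
            all(groups$mu >= 0), all(groups$n_forums >= 1),
            all(groups$members_per_forum >= 1),
            sigma_forum >= 0, sigma_member >= 0,
            fp_rate >= 0, fp_rate <= 1,
            salutation_rate >= 0, salutation_rate <= 1,
            wordcount_min >= 1)
  re_scale <- match.arg(re_scale)
  stopifnot(inherits(lexicon, "absolex_lexicon"))
  if (length(aux_lexicons) > 0L) {
    stopifnot(!is.null(names(aux_lexicons)),
              setequal(names(aux_lexicons), names(aux_rates)),
              all(aux_rates >= 0), all(aux_rates <= 1))
    for (al in aux_lexicons) {
      ov <- intersect(al$words, lexicon$words)
      if (length(ov) > 0L) {
        stop("auxiliary lexicon overlaps the absolutist lexicon: ",
             paste(ov, collapse = ", "))
      }
    }
  }
  structure(list(groups = groups, sigma_forum = sigma_forum,
                 sigma_member = sigma_member,
                 wordcount_meanlog = wordcount_meanlog,
                 wordcount_sdlog = wordcount_sdlog,
                 wordcount_min = as.integer(wordcount_min),
                 fp_rate = fp_rate, salutation_rate = salutation_rate,
                 aux_lexicons = aux_lexicons, aux_rates = aux_rates,
                 sentence_len = as.integer(sentence_len),
                 re_scale = re_scale, lexicon = lexicon,
                 seed = as.integer(seed)),
            class = "absolex_synth_config")
}

rtrunc_lnorm <- function(n, meanlog, sdlog, min) {
  lo <- stats::plnorm(min, meanlog, sdlog)
  pmax(round(stats::qlnorm(stats::runif(n, lo, 1), meanlog, sdlog)),
       min)
}

#' Generate a synthetic nested corpus with known truth
#'
#' Each member's target corrected index is the inverse transform of
#' `transform(mu_g) + forum effect + member effect`, floored at zero.
#' Tokens are then emitted slot by slot: an absolutist word with the
#' member's emission rate (of which a fraction `fp_rate` arrives wrapped in
#' a negation/qualifier phrase, inflating the token count by the extra
#' phrase words), an auxiliary-lexicon word at its configured rate, and a
#' neutral filler word otherwise. Because a phrase occupies more than one
#' token, the per-slot emission rate is solved from the target corrected
#' index so that the expected corrected index equals `mu` after token
#' inflation. Words that appear as context tokens of a false-positive phrase
#' (such as "not", "almost", "hello") are excluded from the filler and
#' auxiliary emission pools, so phrase matches in the generated text are
#' exactly the planted ones and the truth table reconciles with
#' [score_corpus()] counts token for token.
#'
#' @param config An `absolex_synth_config`.
#' @param dir Optional directory; when given, the corpus is written in the
#'   canonical `group/forum/member.txt` layout together with `truth.tsv`.
#' @return List with `tree` (an `absolex_corpus`), `truth` (tibble: one row
#'   per member with the true transformed level `t_member`, the emission
#'   `rate`, realized token and hit counts, and realized raw/fp/corrected
#'   indices), and `dir` (`NULL` unless written).
#' @export
generate_corpus <- function(config, dir = NULL) {
  stopifnot(inherits(config, "absolex_synth_config"))
  set.seed(config$seed)
  lex <- config$lexicon
  fp_ok <- lex$fp_phrases$type %in% c("negation", "qualifier")
  phrases <- lex$fp_phrases[fp_ok, , drop = FALSE]
  sal <- lex$fp_phrases[lex$fp_phrases$type == "salutation", , drop = FALSE]
  fp_rate <- if (nrow(phrases) > 0L) config$fp_rate else 0
  sal_rate <- if (nrow(sal) > 0L) config$salutation_rate else 0
  phrase_len <- lengths(phrases$tokens)
  lbar <- if (nrow(phrases) > 0L) mean(phrase_len) else 1

  context_tokens <- setdiff(unlist(lex$fp_phrases$tokens), lex$words)
  filler <- setdiff(filler_vocabulary(), c(lex$words, context_tokens))
  aux_names <- names(config$aux_lexicons)
  aux_pools <- lapply(config$aux_lexicons,
                      function(al) setdiff(al$words, context_tokens))
  aux_rates <- as.numeric(config$aux_rates[aux_names])

  n_total <- sum(config$groups$n_forums * config$groups$members_per_forum)
  col_group <- character(n_total); col_forum <- character(n_total)
  col_member <- character(n_total); col_text <- character(n_total)
  col_tm <- numeric(n_total); col_rate <- numeric(n_total)
  col_slots <- integer(n_total); col_tok <- integer(n_total)
  col_plain <- integer(n_total); col_fp <- integer(n_total)
  col_aux <- matrix(0L, n_total, length(aux_names))
  i <- 0L
  for (gi in seq_len(nrow(config$groups))) {
    g <- config$groups[gi, ]
    t_g <- transform_index(g$mu)
    for (fi in seq_len(g$n_forums)) {
      e_f <- stats::rnorm(1, 0, config$sigma_forum)
      for (mi in seq_len(g$members_per_forum)) {
        e_m <- stats::rnorm(1, 0, config$sigma_member)
        if (config$re_scale == "transformed") {
          t_m <- t_g + e_f + e_m
          rate <- max(0, 10^t_m - 1) / 100
        } else {
          rate <- max(0, g$mu + e_f + e_m) / 100
          t_m <- transform_index(100 * rate)
        }
        w <- rtrunc_lnorm(1, config$wordcount_meanlog,
                          config$wordcount_sdlog, config$wordcount_min)
        denom <- (1 - fp_rate) - rate * fp_rate * (lbar - 1)
        rho <- if (denom > 0) rate / denom else stop("emission rate > 1")
        p_plain <- rho * (1 - fp_rate)
        p_phr <- rho * fp_rate
        if (p_plain + p_phr + sum(aux_rates) > 1) {
          stop("per-token emission probabilities exceed 1")
        }
        u <- stats::runif(w)
        cuts <- cumsum(c(p_plain, p_phr, aux_rates))
        slot <- findInterval(u, c(0, cuts))  # 1 plain, 2 phrase, 2+j aux j
        units <- character(w)
        is_plain <- slot == 1L
        is_phr <- slot == 2L
        n_plain <- sum(is_plain)
        n_phr <- sum(is_phr)
        if (n_plain > 0L) {
          units[is_plain] <- sample(lex$words, n_plain, replace = TRUE)
        }
        extra <- 0L
        if (n_phr > 0L) {
          pk <- sample.int(nrow(phrases), n_phr, replace = TRUE)
          units[is_phr] <- phrases$phrase[pk]
          extra <- sum(phrase_len[pk] - 1L)
        }
        n_aux <- integer(length(aux_names))
        for (j in seq_along(aux_names)) {
          sel <- slot == 2L + j
          n_aux[j] <- sum(sel)
          if (n_aux[j] > 0L) {
            units[sel] <- sample(aux_pools[[j]], n_aux[j], replace = TRUE)
          }
        }
        rest <- slot > 2L + length(aux_names)
        if (any(rest)) {
          units[rest] <- sample(filler, sum(rest), replace = TRUE)
        }
        has_sal <- sal_rate > 0 && stats::runif(1) < sal_rate
        brk <- seq.int(config$sentence_len, w, by = config$sentence_len)
        units[brk] <- paste0(units[brk], ".")
        if (has_sal) units <- c(paste0(sal$phrase[1L], "."), units)
        i <- i + 1L
        col_group[i] <- g$name
        col_forum[i] <- sprintf("%s_f%d", g$name, fi)
        col_member[i] <- sprintf("m%03d", mi)
        col_text[i] <- paste(units, collapse = " ")
        col_tm[i] <- t_m; col_rate[i] <- rate
        col_slots[i] <- w
        col_tok[i] <- w + extra + if (has_sal) lengths(sal$tokens)[1L] else 0L
        col_plain[i] <- n_plain
        col_fp[i] <- n_phr + as.integer(has_sal)
        if (length(aux_names)) col_aux[i, ] <- n_aux
      }
    }
  }
  tree <- new_corpus(col_group, col_forum, col_member, col_text,
                     word_count = col_tok)
  truth <- tibble::tibble(
    group = col_group, forum = col_forum, member = col_member,
    t_member = col_tm, rate = col_rate, n_slots = col_slots,
    n_tokens = col_tok, n_abs_plain = col_plain, n_fp = col_fp,
    n_abs_raw = col_plain + col_fp,
    raw = 100 * (col_plain + col_fp) / col_tok,
    fp = 100 * col_fp / col_tok,
    corrected = 100 * col_plain / col_tok)
  for (j in seq_along(aux_names)) {
    truth[[paste0("n_", aux_names[j])]] <- col_aux[, j]
  }
  if (!is.null(dir)) {
    write_corpus(tree, dir)
    write_index_table(truth, file.path(dir, "truth.tsv"))
  }
  list(tree = tree, truth = truth, dir = dir)
}

#' Parameter-recovery experiment
#'
#' Runs generate, score and fit per replicate and compares the pipeline's
#' estimates with the generating truth: group means on the transformed
#' scale, the forum variance component, the member-level SD, Cohen's d for a
#' chosen contrast, and the omnibus rejection rate (type-I error under a
#' null configuration, power otherwise). Bias is reported together with the
#' empirical per-replicate SD of each estimator and the Monte-Carlo SE of
#' the bias (`sd / sqrt(replicates)`). Note that the transformed group mean
#' carries a small deterministic attenuation of order 1/(word count) from
#' transforming a noisy index (see the methods vignette), so its bias is
#' judged against the estimator's sampling variability.
#'
#' @param config An `absolex_synth_config`.
#' @param replicates Number of replicates.
#' @param contrast Length-2 character vector of group names for the d /
#'   contrast summaries; defaults to the first two configured groups.
#' @param alpha Omnibus rejection level (default 0.05).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return Object of class `absolex_recovery`: list with `replicates`
#'   (tibble, one row per replicate), `group_summary` (per group: true
#'   transformed mean, mean estimate, bias, sd, mc_se, rmse),
#'   `variance_summary`, `d_mean`, `rejection_rate`, `config`.
#' @export
recovery_experiment <- function(config, replicates, contrast = NULL,
                                alpha = 0.05, seed = config$seed) {
  stopifnot(inherits(config, "absolex_synth_config"), replicates >= 1L)
  gnames <- config$groups$name
  if (is.null(contrast)) contrast <- gnames[1:2]
  stopifnot(length(contrast) == 2L, all(contrast %in% gnames))
  outcome <- paste0(config$lexicon$name, "_corrected")

  one <- function(r) {
    cfg <- config
    cfg$seed <- as.integer(seed + r)
    gen <- generate_corpus(cfg)
    tab <- score_corpus(gen$tree, config$lexicon)
    # singular fits (zero forum variance) are counted, not warned about,
    # inside the Monte-Carlo loop
    fit <- suppressWarnings(fit_mixed(tab, outcome))
    ct <- pairwise_contrast(fit, contrast[1], contrast[2], table = tab)
    means <- stats::setNames(fit$group_means$mean, fit$group_means$group)
    # member-level SD: within-forum SD of the transformed outcome
    # (unweighted; includes the token-sampling component)
    y <- fit$data$y
    f <- fit$data$f
    sig_m <- sqrt(stats::weighted.mean(
      tapply(y, f, stats::var),
      tapply(y, f, length) - 1))
    c(means[gnames],
      sigma_forum = sqrt(unname(fit$varcomp["forum"])),
      sigma_member = sig_m,
      d = ct$d, estimate = ct$estimate,
      p_omnibus = fit$omnibus$p,
      singular = as.numeric(fit$singular))
  }
  reps <- do.call(rbind, lapply(seq_len(replicates), one))
  reps <- tibble::as_tibble(as.data.frame(reps))
  true_t <- transform_index(config$groups$mu)
  gs <- tibble::tibble(
    group = gnames, true_transformed = true_t,
    mean_estimate = colMeans(reps[gnames]),
    bias = colMeans(reps[gnames]) - true_t,
    sd = vapply(reps[gnames], stats::sd, numeric(1)),
    rmse = sqrt(colMeans((t(t(as.matrix(reps[gnames])) - true_t))^2))
  )
  gs$mc_se <- gs$sd / sqrt(replicates)
  vs <- tibble::tibble(
    parameter = c("sigma_forum", "sigma_member"),
    true = c(config$sigma_forum, config$sigma_member),
    mean_estimate = c(mean(reps$sigma_forum), mean(reps$sigma_member)),
    sd = c(stats::sd(reps$sigma_forum), stats::sd(reps$sigma_member))
  )
  vs$bias <- vs$mean_estimate - vs$true
  structure(list(replicates = reps, group_summary = gs,
                 variance_summary = vs,
                 contrast = contrast, d_mean = mean(reps$d),
                 estimate_mean = mean(reps$estimate),
                 rejection_rate = mean(reps$p_omnibus < alpha),
                 singular_rate = mean(reps$singular),
                 alpha = alpha, n_replicates = replicates, config = config),
            class = "absolex_recovery")
}

#' @export
print.absolex_recovery <- function(x, ...) {
  cat(sprintf("<recovery experiment: %d replicates, omnibus rejection rate %.3f at alpha = %.2f>\n",
              x$n_replicates, x$rejection_rate, x$alpha))
  print(x$group_summary)
  print(x$variance_summary)
  cat(sprintf("  contrast %s vs %s: mean estimate %.4f, mean d %.3f\n",
              x$contrast[1], x$contrast[2], x$estimate_mean, x$d_mean))
  invisible(x)
}
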