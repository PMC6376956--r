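#' Positive-skew correcting transform
#'
#' `log10(x + 1)`; adding 1 keeps zero indices at zero and the transform
#' strictly monotone on the nonnegative half-line. Maps 0, 9, 99 to 0, 1, 2.
#'
#' @param x Nonnegative numeric (percentage indices).
#' @return Transformed values.
#' @export
transform_index <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("transform_index() requires x >= 0")
  log10(x + 1)
}

# Assemble the analysis frame shared by fit_mixed / bootstrap / sensitivity.
analysis_frame <- function(table, outcome, covariates = NULL,
                           transform = TRUE, weights = TRUE) {
  stopifnot(is.data.frame(table), outcome %in% names(table))
  if (!all(c("group", "forum", "word_count") %in% names(table))) {
    stop("index table must have columns group, forum, word_count")
  }
  d <- data.frame(
    y = if (transform) transform_index(table[[outcome]]) else table[[outcome]],
    g = factor(table$group),
    # forums are nested in groups; a composite id makes the nesting explicit
    f = factor(paste(table$group, table$forum, sep = "/")),
    w = if (weights) table$word_count else rep(1, nrow(table))
  )
  if (!is.null(covariates)) {
    for (cv in covariates) {
      if (!cv %in% names(table)) stop("covariate not in table: ", cv)
      if (identical(cv, outcome)) stop("covariate equals outcome: ", cv)
      v <- table[[cv]]
      if (stats::var(v) == 0) stop("constant covariate: ", cv)
      d[[paste0("c_", make.names(cv))]] <-
        if (transform) transform_index(v) else v
    }
    cvn <- grep("^c_", names(d), value = TRUE)
    if (length(cvn) > 1L) {
      cc <- stats::cor(d[cvn])
      bad <- which(abs(cc) > 0.999 & row(cc) < col(cc), arr.ind = TRUE)
      if (nrow(bad) > 0L) {
        stop("collinear covariates: ",
             covariates[bad[1, 1]], " and ", covariates[bad[1, 2]])
      }
    }
  }
  d
}

#' Fit the nested mixed-effects group model
#'
#' Fits `y ~ group (+ covariates) + (1 | forum)` to a member-level index
#' table, where `y` is the (by default log10(x+1)-transformed) outcome index
#' and residuals are weighted by each member's word count. Forums contribute
#' random intercepts nested in groups; the omnibus test of the group factor
#' uses Satterthwaite denominator degrees of freedom. With
#' `forum_re = FALSE` the forum variance component is forced to zero and the
#' model reduces to a weighted fixed-effects ANOVA/ANCOVA.
#'
#' @param table An index table (see [score_corpus()]): needs columns `group`,
#'   `forum`, `word_count`, and the outcome.
#' @param outcome Name of the outcome column (e.g.
#'   `"absolutist_corrected"`).
#' @param covariates Optional character vector of covariate index columns
#'   (transformed on the same scale as the outcome).
#' @param transform Apply [transform_index()] to outcome and covariates
#'   (default `TRUE`).
#' @param weights Weight residuals by member word count (default `TRUE`).
#' @param forum_re Include the forum random intercept (default `TRUE`).
#' @param reml Use REML for variance components (default `TRUE`); maximum
#'   likelihood is appropriate when comparing nested fixed-effect models.
#' @return Object of class `absolex_fit`: list with `model`, `omnibus`
#'   (list `F`, `df1`, `df2`, `p`), `group_means` (tibble of adjusted means
#'   on the transformed scale with SE and df), `varcomp` (named vector,
#'   forum and residual), `singular`, `data`, plus the call settings.
#' @export
fit_mixed <- function(table, outcome, covariates = NULL, transform = TRUE,
                      weights = TRUE, forum_re = TRUE, reml = TRUE) {
  d <- analysis_frame(table, outcome, covariates, transform, weights)
  if (nlevels(d$g) < 2L) stop("need >= 2 groups for the omnibus test")
  cvn <- grep("^c_", names(d), value = TRUE)
  rhs <- paste(c("g", cvn), collapse = " + ")

  if (stats::var(d$y) == 0) {
    # degenerate outcome: no variance to explain on any scale
    lev <- levels(d$g)
    gm <- tibble::tibble(group = lev, mean = rep(d$y[1], length(lev)),
                         se = 0, df = NA_real_)
    out <- list(model = NULL,
                omnibus = list(F = 0, df1 = nlevels(d$g) - 1L,
                               df2 = NA_real_, p = 1),
                group_means = gm,
                varcomp = c(forum = 0, residual = 0),
                singular = TRUE, data = d, outcome = outcome,
                transform = transform, weights = weights,
                forum_re = forum_re, covariates = covariates)
    class(out) <- "absolex_fit"
    return(out)
  }

  if (forum_re) {
    fml <- stats::as.formula(paste("y ~", rhs, "+ (1 | f)"))
    model <- suppressMessages(
      lmerTest::lmer(fml, data = d, weights = w, REML = reml))
    singular <- lme4::isSingular(model)
    if (singular) {
      warning("singular fit: forum variance component estimated at zero")
    }
    av <- suppressMessages(stats::anova(model, type = 3,
                                        ddf = "Satterthwaite"))
    row <- which(rownames(av) == "g")
    omnibus <- list(F = av[row, "F value"], df1 = av[row, "NumDF"],
                    df2 = av[row, "DenDF"], p = av[row, "Pr(>F)"])
    vc <- as.data.frame(lme4::VarCorr(model))
    varcomp <- c(forum = vc$vcov[vc$grp == "f"],
                 residual = vc$vcov[vc$grp == "Residual"])
  } else {
    model <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = d,
                       weights = w)
    m0 <- stats::lm(stats::as.formula(
      if (length(cvn)) paste("y ~", paste(cvn, collapse = " + ")) else "y ~ 1"),
      data = d, weights = w)
    av <- stats::anova(m0, model)
    omnibus <- list(F = av$F[2], df1 = av$Df[2], df2 = av$Res.Df[2],
                    p = av$`Pr(>F)`[2])
    if (!is.finite(omnibus$F) &&
        abs(av$`Sum of Sq`[2]) < 1e-10 * max(sum(d$w * d$y^2), 1)) {
      # covariates explain the outcome exactly: no group effect left
      omnibus$F <- 0
      omnibus$p <- 1
    }
    singular <- FALSE
    varcomp <- c(forum = 0,
                 residual = sum(d$w * stats::resid(model)^2) /
                   stats::df.residual(model))
  }
  emm <- emmeans::emmeans(model, "g", lmer.df = "satterthwaite",
                          lmerTest.limit = 1e6)
  es <- as.data.frame(emm)
  out <- list(model = model, omnibus = omnibus,
              group_means = tibble::tibble(group = as.character(es$g),
                                           mean = es$emmean, se = es$SE,
                                           df = es$df),
              varcomp = varcomp, singular = singular, data = d,
              outcome = outcome, transform = transform, weights = weights,
              forum_re = forum_re, covariates = covariates)
  class(out) <- "absolex_fit"
  out
}

#' @export
print.absolex_fit <- function(x, ...) {
  cat(sprintf("<mixed-model fit: %s ~ group%s%s>\n", x$outcome,
              if (length(x$covariates)) " + covariates" else "",
              if (x$forum_re) " + (1 | forum)" else ""))
  cat(sprintf("  omnibus F(%s, %s) = %.3f, p = %.4g\n",
              format(x$omnibus$df1), format(round(x$omnibus$df2, 1)),
              x$omnibus$F, x$omnibus$p))
  cat(sprintf("  variance components: forum %.4g, residual %.4g%s\n",
              x$varcomp["forum"], x$varcomp["residual"],
              if (x$singular) " (singular)" else ""))
  print(x$group_means)
  invisible(x)
}

#' Pairwise group contrast with effect size
#'
#' Difference of adjusted group means (group `b` minus group `a`) on the
#' model scale, with a model-based standard error and Satterthwaite degrees
#' of freedom. Cohen's d is reported as a magnitude: the absolute mean
#' difference divided by the pooled member-level SD of the outcome across
#' the two groups, on the transformed scale by default (`d_scale = "raw"`
#' uses the untransformed percentages). Raw-scale descriptives (M, SD per
#' group) are always attached for interpretability.
#'
#' @param fit An `absolex_fit`.
#' @param a,b Group names to contrast (estimate is `mean(b) - mean(a)`).
#' @param table The index table the model was fitted to (used for pooled
#'   SDs and raw descriptives). Defaults to the frame stored in `fit`,
#'   which lacks raw-scale values if `transform = TRUE`; pass the original
#'   table to get raw descriptives.
#' @param correction `"none"` or `"bonferroni"`.
#' @param m Number of comparisons for the Bonferroni correction.
#' @param d_scale `"transformed"` (default) or `"raw"`.
#' @return Object of class `absolex_contrast`: list with `a`, `b`,
#'   `estimate`, `se`, `df`, `t`, `p`, `p_adj`, `d`, `descriptives` (tibble)
#'   and optionally `ci` once [stratified_bootstrap_ci()] is attached.
#' @export
pairwise_contrast <- function(fit, a, b, table = NULL,
                              correction = c("none", "bonferroni"), m = 1L,
                              d_scale = c("transformed", "raw")) {
  stopifnot(inherits(fit, "absolex_fit"))
  correction <- match.arg(correction)
  d_scale <- match.arg(d_scale)
  lev <- fit$group_means$group
  if (!a %in% lev || !b %in% lev) stop("unknown group in contrast")
  if (identical(a, b)) stop("contrast requires two distinct groups")

  if (is.null(fit$model)) {
    est <- 0; se <- 0; tval <- 0; df <- NA_real_; p <- 1
  } else {
    emm <- emmeans::emmeans(fit$model, "g", lmer.df = "satterthwaite",
                            lmerTest.limit = 1e6)
    k <- as.integer(factor(c(a, b), levels = lev))
    cvec <- numeric(length(lev)); cvec[k[2]] <- 1; cvec[k[1]] <- -1
    ct <- as.data.frame(emmeans::contrast(
      emm, method = list(diff = cvec)))
    est <- ct$estimate; se <- ct$SE; tval <- ct$t.ratio; df <- ct$df
    p <- ct$p.value
  }
  p_adj <- if (correction == "bonferroni") min(1, m * p) else p

  src <- if (is.null(table)) NULL else table
  if (!is.null(src)) {
    ya <- src[[fit$outcome]][src$group == a]
    yb <- src[[fit$outcome]][src$group == b]
    desc <- tibble::tibble(group = c(a, b),
                           n = c(length(ya), length(yb)),
                           M = c(mean(ya), mean(yb)),
                           SD = c(stats::sd(ya), stats::sd(yb)))
    ta <- if (fit$transform) transform_index(ya) else ya
    tb <- if (fit$transform) transform_index(yb) else yb
  } else {
    ta <- fit$data$y[fit$data$g == a]
    tb <- fit$data$y[fit$data$g == b]
    desc <- tibble::tibble(group = c(a, b), n = c(length(ta), length(tb)),
                           M = NA_real_, SD = NA_real_)
  }
  if (d_scale == "transformed") {
    num <- abs(est)
    pooled <- pooled_sd(ta, tb)
  } else {
    if (is.null(src)) stop("d_scale = 'raw' needs the original index table")
    num <- abs(mean(yb) - mean(ya))
    pooled <- pooled_sd(ya, yb)
  }
  d <- if (pooled > 0) num / pooled else 0

  structure(list(a = a, b = b, estimate = est, se = se, t = tval, df = df,
                 p = p, p_adj = p_adj, correction = correction, m = m,
                 d = d, d_scale = d_scale, descriptives = desc, ci = NULL),
            class = "absolex_contrast")
}

pooled_sd <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2))
}

#' @export
print.absolex_contrast <- function(x, ...) {
  cat(sprintf("<contrast %s vs %s: diff = %.4f (SE %.4f), t(%.1f) = %.2f, p = %.4g%s, d = %.2f (%s scale)>\n",
              x$a, x$b, x$estimate, x$se, x$df, x$t, x$p_adj,
              if (x$correction != "none") paste0(" [", x$correction, "]") else "",
              x$d, x$d_scale))
  if (!is.null(x$ci)) {
    cat(sprintf("  bootstrap %g%% BCa CI: [%.4f, %.4f] (B = %d)\n",
                100 * x$ci$level, x$ci$lower, x$ci$upper, x$ci$B))
  }
  invisible(x)
}

#' Analysis of covariance for a lexicon index
#'
#' Group effect on the transformed outcome after adjusting for other
#' transformed lexicon indices (for instance certainty, negative-emotion and
#' pronoun indices), in the same weighted nested mixed model.
#'
#' @inheritParams fit_mixed
#' @param covariates Character vector of covariate index columns (must
#'   differ from the outcome, non-constant, not collinear).
#' @return An `absolex_fit` whose omnibus test is the adjusted group effect.
#' @export
ancova <- function(table, outcome, covariates, transform = TRUE,
                   weights = TRUE, forum_re = TRUE, reml = TRUE) {
  if (length(covariates) == 0L) stop("ancova() needs covariates")
  fit_mixed(table, outcome, covariates = covariates, transform = transform,
            weights = weights, forum_re = forum_re, reml = reml)
}

#' Leave-one-forum-out sensitivity analysis
#'
#' Refits the model and recomputes a set of pairwise contrasts after
#' excluding each forum of a probed group in turn, and summarizes the
#' min-max range of Cohen's d and p across the refits.
#'
#' @param table Index table.
#' @param outcome Outcome column.
#' @param probe_group Group whose forums are excluded one at a time (needs
#'   at least two forums).
#' @param contrasts List of length-2 character vectors `c(a, b)`.
#' @param d_scale,transform,weights,forum_re,reml Passed through to
#'   [fit_mixed()] / [pairwise_contrast()].
#' @return Object of class `absolex_sensitivity`: list with `results` (one
#'   tibble row per excluded forum x contrast), `summary` (per contrast:
#'   min/max of d and p), and `full` (the all-forums contrasts).
#' @export
leave_one_forum_out <- function(table, outcome, probe_group, contrasts,
                                d_scale = "transformed", transform = TRUE,
                                weights = TRUE, forum_re = TRUE, reml = TRUE) {
  stopifnot(is.list(contrasts), length(contrasts) > 0L)
  forums <- unique(table$forum[table$group == probe_group])
  if (length(forums) < 2L) {
    stop("probe group '", probe_group, "' has fewer than 2 forums")
  }
  run_contrasts <- function(tab) {
    fit <- fit_mixed(tab, outcome, transform = transform, weights = weights,
                     forum_re = forum_re, reml = reml)
    do.call(rbind, lapply(contrasts, function(pr) {
      ct <- pairwise_contrast(fit, pr[1], pr[2], table = tab,
                              d_scale = d_scale)
      tibble::tibble(a = pr[1], b = pr[2], estimate = ct$estimate,
                     p = ct$p, d = ct$d)
    }))
  }
  full <- run_contrasts(table)
  res <- do.call(rbind, lapply(forums, function(fo) {
    sub <- table[!(table$group == probe_group & table$forum == fo), ]
    cbind(tibble::tibble(excluded_forum = fo), run_contrasts(sub))
  }))
  key <- paste(res$a, res$b, sep = " vs ")
  summ <- do.call(rbind, lapply(unique(key), function(k) {
    r <- res[key == k, ]
    tibble::tibble(contrast = k, n_refits = nrow(r),
                   d_min = min(r$d), d_max = max(r$d),
                   p_min = min(r$p), p_max = max(r$p))
  }))
  structure(list(results = res, summary = summ, full = full,
                 probe_group = probe_group, forums = forums),
            class = "absolex_sensitivity")
}

#' @export
print.absolex_sensitivity <- function(x, ...) {
  cat(sprintf("<sensitivity: %d refits, one per forum of '%s'>\n",
              length(x$forums), x$probe_group))
  print(x$summary)
  invisible(x)
}
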