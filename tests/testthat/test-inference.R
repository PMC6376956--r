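test_that("the log10(x+1) transform hits its identities and rejects negatives", {
  expect_identical(transform_index(c(0, 9, 99)), c(0, 1, 2))
  expect_error(transform_index(-0.1), "x >= 0")
  # strictly monotone
  x <- sort(stats::runif(50, 0, 30))
  expect_true(all(diff(transform_index(x)) > 0))
})

test_that("with the forum variance forced to zero the omnibus F equals the
          closed-form weighted one-way ANOVA", {
  tab <- make_index_table(c("g1", "g2", "g3"), 2, 10, function(n, g, f) {
    stats::rlnorm(n, meanlog = c(g1 = 0, g2 = 0.2, g3 = 0.4)[g], sdlog = 0.4)
  }, word_counts = sample(100:900, 60, replace = TRUE), seed = 5)
  fit <- fit_mixed(tab, "score", forum_re = FALSE)
  y <- transform_index(tab$score)
  expect_equal(fit$omnibus$F,
               oracle_weighted_anova_F(y, tab$group, tab$word_count),
               tolerance = 1e-6)
  expect_equal(fit$omnibus$df1, 2L)
  expect_equal(fit$omnibus$df2, 57L)
  expect_equal(fit$varcomp[["forum"]], 0)
})

test_that("a constant outcome yields F = 0, p = 1 instead of a crash", {
  tab <- make_index_table(c("a", "b"), 2, 5, function(n, g, f) rep(2, n))
  fit <- fit_mixed(tab, "score")
  expect_equal(fit$omnibus$F, 0)
  expect_equal(fit$omnibus$p, 1)
  ct <- pairwise_contrast(fit, "a", "b", table = tab)
  expect_equal(ct$estimate, 0)
  expect_equal(ct$d, 0)
})

test_that("mixed fit recovers group means and the omnibus test responds to
          separation", {
  # forum effects present: mixed model must not crash nor mis-order means
  tab <- make_index_table(c("lo", "hi"), 4, 30, function(n, g, f) {
    mu <- ifelse(g == "hi", 1.8, 0.9)
    fx <- stats::rnorm(8, 0, 0.05)[as.integer(interaction(g, f))]
    pmax(0, 10^(transform_index(mu) + fx + stats::rnorm(n, 0, 0.15)) - 1)
  }, seed = 21)
  fit <- fit_mixed(tab, "score")
  gm <- stats::setNames(fit$group_means$mean, fit$group_means$group)
  expect_gt(gm[["hi"]], gm[["lo"]])
  expect_lt(fit$omnibus$p, 0.01)
  expect_gte(fit$varcomp[["forum"]], 0)
  expect_error(fit_mixed(tab[tab$group == "lo", ], "score"), ">= 2 groups")
})

test_that("pairwise contrasts carry effect sizes and Bonferroni arithmetic", {
  # two groups exactly one pooled SD apart on the analysis scale
  set.seed(31)
  n <- 500
  tab <- tibble::tibble(
    group = rep(c("a", "b"), each = n),
    forum = rep(c("a_f1", "a_f2", "b_f1", "b_f2"), each = n / 2),
    member = paste0("m", 1:(2 * n)),
    word_count = 300,
    score = c(stats::rnorm(n, 5, 1), stats::rnorm(n, 6, 1))
  )
  # two forums per group with no true forum effect: a singular (zero) forum
  # variance is the expected estimate here
  fit <- suppressWarnings(
    fit_mixed(tab, "score", transform = FALSE, weights = FALSE))
  ct <- pairwise_contrast(fit, "a", "b", table = tab)
  expect_equal(ct$estimate, 1, tolerance = 0.15)
  expect_equal(ct$d, 1, tolerance = 0.15)
  expect_gt(ct$d, 0)
  # estimate is directional (b - a), d is a magnitude
  ct_rev <- pairwise_contrast(fit, "b", "a", table = tab)
  expect_equal(ct_rev$estimate, -ct$estimate)
  expect_equal(ct_rev$d, ct$d)
  # Bonferroni: p_adj = min(1, m p)
  ct6 <- pairwise_contrast(fit, "a", "b", table = tab,
                           correction = "bonferroni", m = 6)
  expect_equal(ct6$p_adj, min(1, 6 * ct6$p))
  expect_equal(min(1, 6 * 0.04), 0.24)  # the documented arithmetic
  expect_error(pairwise_contrast(fit, "a", "a"), "distinct groups")
  # raw-scale d uses raw descriptives
  ctr <- pairwise_contrast(fit, "a", "b", table = tab, d_scale = "raw")
  expect_equal(ctr$d,
               abs(mean(tab$score[tab$group == "b"]) -
                     mean(tab$score[tab$group == "a"])) /
                 absolex:::pooled_sd(tab$score[tab$group == "a"],
                                     tab$score[tab$group == "b"]))
})

test_that("identical groups give a near-zero effect size", {
  set.seed(17)
  tab <- make_index_table(c("a", "b"), 2, 250, function(n, g, f) {
    stats::rlnorm(n, 0, 0.3)
  })
  fit <- suppressWarnings(fit_mixed(tab, "score", weights = FALSE))
  ct <- pairwise_contrast(fit, "a", "b", table = tab)
  expect_lt(abs(ct$d), 0.1)
})

test_that("ancova adjusts for covariates and validates them", {
  set.seed(41)
  # covariate independent of group and outcome: adjusted F ~ unadjusted F
  tab <- make_index_table(c("a", "b"), 3, 40, function(n, g, f) {
    pmax(0, 10^(ifelse(g == "b", 0.45, 0.30) + stats::rnorm(n, 0, 0.15)) - 1)
  })
  tab$cov <- stats::rlnorm(nrow(tab), 0.5, 0.3)
  f0 <- fit_mixed(tab, "score")
  f1 <- ancova(tab, "score", "cov")
  expect_equal(f1$omnibus$F, f0$omnibus$F, tolerance = 0.25)
  expect_lt(f1$omnibus$p, 0.05)

  # outcome an exact linear function of the covariate: group effect vanishes
  tab2 <- make_index_table(c("a", "b"), 2, 30, function(n, g, f) {
    stats::rlnorm(n, 0, 0.3)
  }, seed = 8)
  tab2$cov <- 3 * tab2$score
  f2 <- ancova(tab2, "score", "cov", transform = FALSE, forum_re = FALSE)
  expect_gt(f2$omnibus$p, 0.9)

  tab$flat <- 1
  expect_error(ancova(tab, "score", "flat"), "constant covariate")
  tab$cov2 <- tab$cov
  expect_error(ancova(tab, "score", c("cov", "cov2")), "collinear")
  expect_error(ancova(tab, "score", "score"), "covariate equals outcome")
  expect_error(ancova(tab, "score", character()), "needs covariates")
})

test_that("leave-one-forum-out produces one refit per forum with sane ranges", {
  set.seed(77)
  tab <- make_index_table(c("ctrl", "probe"), 4, 25, function(n, g, f) {
    pmax(0, 10^(ifelse(g == "probe", 0.45, 0.30) +
                  stats::rnorm(n, 0, 0.15)) - 1)
  })
  # refits on small subsets may legitimately estimate a zero forum variance
  rep_out <- suppressWarnings(
    leave_one_forum_out(tab, "score", "probe", list(c("ctrl", "probe"))))
  expect_equal(length(rep_out$forums), 4L)
  expect_equal(nrow(rep_out$results), 4L)
  expect_equal(rep_out$summary$n_refits, 4L)
  # homogeneous forums: the all-forums d lies inside the excluded-forum range
  expect_gte(rep_out$full$d, rep_out$summary$d_min)
  expect_lte(rep_out$full$d, rep_out$summary$d_max)
  expect_error(leave_one_forum_out(tab, "score", "nope", list(c("a", "b"))),
               "fewer than 2 forums")

  # excluding either of two identical forums leaves identical estimates
  dup <- tab
  dup[dup$group == "probe" & dup$forum == "probe_f2", "score"] <-
    dup[dup$group == "probe" & dup$forum == "probe_f1", "score"]
  r2 <- suppressWarnings(
    leave_one_forum_out(dup, "score", "probe", list(c("ctrl", "probe"))))
  est <- r2$results$estimate[r2$results$excluded_forum %in%
                               c("probe_f1", "probe_f2")]
  expect_equal(est[1], est[2], tolerance = 1e-9)
})
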