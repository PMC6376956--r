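# Quantile of a bootstrap distribution by interpolation on the normal
# quantile scale (the usual convention for BCa endpoints): the k-th order
# statistic sits at plotting position k / (B + 1).
boot_quantile <- function(t, alpha) {
  t <- sort(t)
  B <- length(t)
  vapply(alpha, function(a) {
    rk <- (B + 1) * a
    if (rk <= 1) return(t[1L])
    if (rk >= B) return(t[B])
    k <- floor(rk)
    lo <- stats::qnorm(k / (B + 1))
    hi <- stats::qnorm((k + 1) / (B + 1))
    t[k] + (stats::qnorm(a) - lo) / (hi - lo) * (t[k + 1] - t[k])
  }, numeric(1))
}

# BCa interval machinery, exposed with overridable z0/acceleration so the
# analytic reduction (z0 = 0, a = 0 => percentile interval) is testable.
bca_interval <- function(t0, boots, jack = NULL, level = 0.95,
                         z0 = NULL, accel = NULL) {
  boots <- boots[is.finite(boots)]
  B <- length(boots)
  if (B < 1L) stop("no usable bootstrap replicates")
  if (stats::var(boots) == 0 && boots[1] == t0) {
    return(list(lower = t0, upper = t0, z0 = 0, accel = 0))
  }
  if (is.null(z0)) {
    pr <- (sum(boots < t0) + 0.5 * sum(boots == t0)) / B
    pr <- min(max(pr, 1 / (2 * B)), 1 - 1 / (2 * B))
    z0 <- stats::qnorm(pr)
  }
  if (is.null(accel)) {
    if (is.null(jack)) stop("jackknife values needed for acceleration")
    u <- mean(jack) - jack
    denom <- sum(u^2)^1.5
    accel <- if (denom > 0) sum(u^3) / (6 * denom) else 0
  }
  alpha <- (1 + c(-level, level)) / 2
  if (z0 == 0 && accel == 0) {
    # analytic reduction: the BCa map is the identity and the interval is
    # exactly the percentile interval
    adj <- alpha
  } else {
    zal <- stats::qnorm(alpha)
    adj <- stats::pnorm(z0 + (z0 + zal) / (1 - accel * (z0 + zal)))
  }
  ends <- boot_quantile(boots, adj)
  list(lower = ends[1], upper = ends[2], z0 = z0, accel = accel)
}

#' Stratified BCa bootstrap confidence interval for a group contrast
#'
#' Resamples members with replacement within each forum (forums are the
#' strata), recomputes the contrast statistic per resample, and forms a
#' bias-corrected and accelerated (BCa) interval: the bias correction `z0`
#' comes from the share of the bootstrap distribution below the observed
#' statistic, and the acceleration `a` from a jackknife over members. The
#' default statistic is the word-count-weighted difference of transformed
#' group means, `mean(b) - mean(a)` (the scale on which the model's
#' contrasts live); `statistic = "model"` refits the full mixed model per
#' resample instead.
#'
#' @param table Index table.
#' @param outcome Outcome column.
#' @param a,b Groups to contrast (statistic is `mean(b) - mean(a)`).
#' @param B Number of resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; the interval is reproducible given the seed.
#' @param statistic `"mean_diff"` (default) or `"model"` (full refit per
#'   resample; slow).
#' @param transform,weights Passed to the statistic.
#' @param z0,accel Optional overrides of the bias-correction and
#'   acceleration constants (used for analytic reduction tests; with both 0
#'   the interval is the percentile interval).
#' @return Object of class `absolex_bootstrap_ci`: list with `lower`,
#'   `upper`, `level`, `method = "BCa"`, `B`, `seed`, `t0`, `z0`, `accel`.
#' @export
stratified_bootstrap_ci <- function(table, outcome, a, b, B = 1000L,
                                    level = 0.95, seed = 20180105L,
                                    statistic = c("mean_diff", "model"),
                                    transform = TRUE, weights = TRUE,
                                    z0 = NULL, accel = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(B >= 1L, level > 0, level < 1)
  sub <- table[table$group %in% c(a, b), , drop = FALSE]
  if (!all(c(a, b) %in% sub$group)) stop("unknown group in contrast")
  y <- if (transform) transform_index(sub[[outcome]]) else sub[[outcome]]
  w <- if (weights) sub$word_count else rep(1, nrow(sub))
  gb <- sub$group == b
  strata <- factor(paste(sub$group, sub$forum, sep = "/"))
  idx_by_stratum <- split(seq_len(nrow(sub)), strata)
  if (any(lengths(idx_by_stratum) == 0L)) stop("empty stratum")

  stat_mean_diff <- function(idx) {
    yi <- y[idx]; wi <- w[idx]; bi <- gb[idx]
    if (!any(bi) || !any(!bi)) return(NA_real_)
    sum(yi[bi] * wi[bi]) / sum(wi[bi]) - sum(yi[!bi] * wi[!bi]) / sum(wi[!bi])
  }
  stat_model <- function(idx) {
    tab <- sub[idx, , drop = FALSE]
    if (length(unique(tab$group)) < 2L) return(NA_real_)
    fit <- try(fit_mixed(tab, outcome, transform = transform,
                         weights = weights), silent = TRUE)
    if (inherits(fit, "try-error")) return(NA_real_)
    gm <- fit$group_means
    gm$mean[gm$group == b] - gm$mean[gm$group == a]
  }
  stat <- if (statistic == "mean_diff") stat_mean_diff else stat_model

  t0 <- stat(seq_len(nrow(sub)))
  set.seed(seed)
  boots <- vapply(seq_len(B), function(i) {
    idx <- unlist(lapply(idx_by_stratum,
                         function(s) s[sample.int(length(s), length(s),
                                                  replace = TRUE)]),
                  use.names = FALSE)
    stat(idx)
  }, numeric(1))
  if (mean(!is.finite(boots)) > 0.5) {
    stop("statistic degenerate on more than half of the resamples")
  }
  jack <- NULL
  if (is.null(accel)) {
    n <- nrow(sub)
    jack <- vapply(seq_len(n), function(i) stat(setdiff(seq_len(n), i)),
                   numeric(1))
  }
  ci <- bca_interval(t0, boots, jack = jack, level = level, z0 = z0,
                     accel = accel)
  structure(list(lower = ci$lower, upper = ci$upper, level = level,
                 method = "BCa", B = B, seed = seed, t0 = t0,
                 z0 = ci$z0, accel = ci$accel, statistic = statistic),
            class = "absolex_bootstrap_ci")
}

#' @export
print.absolex_bootstrap_ci <- function(x, ...) {
  cat(sprintf("<%g%% %s bootstrap CI: [%.4f, %.4f] (B = %d, seed = %d)>\n",
              100 * x$level, x$method, x$lower, x$upper, x$B, x$seed))
  invisible(x)
}
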