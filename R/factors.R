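# Smooth a correlation matrix that is not positive definite: clip
# eigenvalues at a small floor and rescale to unit diagonal.
smooth_correlation <- function(R, floor = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) > floor) return(R)
  warning("correlation matrix not positive definite; eigenvalue smoothing applied")
  v <- pmax(e$values, floor)
  S <- e$vectors %*% diag(v, length(v)) %*% t(e$vectors)
  D <- diag(1 / sqrt(diag(S)), nrow(S))
  S <- D %*% S %*% D
  dimnames(S) <- dimnames(R)
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < floor / 10) {
    stop("correlation matrix remains degenerate after smoothing")
  }
  S
}

# Principal-axis factoring: iterate communalities starting from squared
# multiple correlations until the communality vector stabilizes.
principal_axis <- function(R, n_factors, max_iter = 200L, tol = 1e-7) {
  p <- ncol(R)
  inv <- try(solve(R), silent = TRUE)
  h2 <- if (inherits(inv, "try-error")) rep(0.5, p) else 1 - 1 / diag(inv)
  h2 <- pmin(pmax(h2, 0.05), 0.999)
  L <- NULL
  for (it in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    k <- seq_len(n_factors)
    L <- e$vectors[, k, drop = FALSE] %*%
      diag(sqrt(pmax(e$values[k], 0)), n_factors)
    h2_new <- pmin(rowSums(L^2), 0.999)
    if (max(abs(h2_new - h2)) < tol) {
      h2 <- h2_new
      break
    }
    h2 <- h2_new
  }
  rownames(L) <- rownames(R)
  list(loadings = L, communalities = h2, iterations = it,
       converged = it < max_iter)
}

# Quartimin criterion (direct oblimin with gamma = 0) and its gradient.
quartimin_vgQ <- function(L) {
  k <- ncol(L)
  L2 <- L^2
  N <- matrix(1, k, k) - diag(k)
  list(f = sum(L2 * (L2 %*% N)) / 4, Gq = L * (L2 %*% N))
}

# Gradient-projection algorithm for oblique rotation (Bernaards & Jennrich).
gpa_oblique <- function(A, vgQ = quartimin_vgQ, Tmat = diag(ncol(A)),
                        max_iter = 1000L, tol = 1e-6) {
  al <- 1
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  VgQ <- vgQ(L)
  f <- VgQ$f
  G <- -t(t(L) %*% VgQ$Gq %*% Ti)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), ncol(A))
    s <- sqrt(sum(Gp^2))
    if (s < tol) {
      converged <- TRUE
      break
    }
    al <- 2 * al
    for (half in seq_len(50L)) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), ncol(A))
      Ti <- solve(Tt)
      L <- A %*% t(Ti)
      VgQt <- vgQ(L)
      if (VgQt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    f <- VgQt$f
    G <- -t(t(L) %*% VgQt$Gq %*% Ti)
  }
  list(loadings = L, Phi = t(Tmat) %*% Tmat, Tmat = Tmat, f = f,
       converged = converged, iterations = iter)
}

#' Exploratory factor analysis with direct oblimin rotation
#'
#' Principal-axis extraction followed by a direct oblimin (quartimin)
#' rotation via the gradient-projection algorithm, returning the full
#' pattern matrix, the factor correlation matrix, and a view filtered at a
#' loadings cutoff (only entries with `|loading| > cutoff` are retained).
#' The extraction is exploratory: oblique rotation with a cutoff is the
#' standard way to inspect which words travel together, with a confirmatory
#' measurement model ([cfa_one_factor()]) reserved for the retained items.
#'
#' @param x A per-word index matrix: numeric matrix or data frame; non-
#'   numeric id columns (`group`, `forum`, `member`) are dropped.
#' @param n_factors Number of factors to extract.
#' @param cutoff Loadings cutoff for the filtered view (default 0.55).
#' @return Object of class `absolex_loadings`: list with `loadings` (p x k
#'   pattern matrix), `Phi` (factor correlations), `filtered` (loadings with
#'   sub-cutoff entries set to `NA`), `communalities`, `cutoff`,
#'   `rotation`, `converged`.
#' @export
efa_oblimin <- function(x, n_factors, cutoff = 0.55) {
  stopifnot(n_factors >= 1L)
  m <- as.matrix(as.data.frame(x)[vapply(as.data.frame(x), is.numeric,
                                         logical(1))])
  if (ncol(m) < n_factors) stop("more factors than variables")
  keep <- apply(m, 2, stats::var) > 0
  if (!all(keep)) {
    warning("dropping zero-variance columns: ",
            paste(colnames(m)[!keep], collapse = ", "))
    m <- m[, keep, drop = FALSE]
  }
  R <- smooth_correlation(stats::cor(m))
  pa <- principal_axis(R, n_factors)
  if (n_factors == 1L) {
    L <- pa$loadings
    Phi <- matrix(1, 1, 1)
    converged <- pa$converged
  } else {
    rot <- gpa_oblique(pa$loadings)
    L <- rot$loadings
    Phi <- rot$Phi
    converged <- pa$converged && rot$converged
  }
  # sign indeterminacy: orient each factor so its largest loading is positive
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) {
      L[, j] <- -L[, j]
      Phi[j, ] <- -Phi[j, ]
      Phi[, j] <- -Phi[, j]
    }
  }
  colnames(L) <- paste0("F", seq_len(ncol(L)))
  dimnames(Phi) <- list(colnames(L), colnames(L))
  filtered <- L
  filtered[abs(filtered) <= cutoff] <- NA_real_
  structure(list(loadings = L, Phi = Phi, filtered = filtered,
                 communalities = pa$communalities, cutoff = cutoff,
                 rotation = if (n_factors == 1L) "none" else "oblimin",
                 n_factors = n_factors, converged = converged),
            class = "absolex_loadings")
}

#' @export
print.absolex_loadings <- function(x, digits = 3, ...) {
  cat(sprintf("<EFA: %d factors, %s rotation, cutoff %.2f>\n",
              x$n_factors, x$rotation, x$cutoff))
  print(round(x$loadings, digits))
  if (x$n_factors > 1L) {
    cat("factor correlations:\n")
    print(round(x$Phi, digits))
  }
  invisible(x)
}

#' One-factor confirmatory measurement model
#'
#' Fits a single-factor model by maximum likelihood (loadings and
#' uniquenesses free, factor variance fixed at 1) and reports the chi-square
#' test of exact fit with `df = p(p+1)/2 - 2p`, plus GFI, CFI and NFI
#' against the independence baseline. GFI is defined through the ML fit
#' function as `1 - tr((solve(Sigma) %*% S - I)^2) / tr((solve(Sigma) %*% S)^2)`.
#' The first indicator's loading is fixed positive (sign canonicalization).
#'
#' @param x Per-word index matrix (matrix or data frame; id columns dropped),
#'   or a covariance matrix if `n_obs` is given.
#' @param words Character vector of indicator columns (e.g. the 7 highest
#'   loading words from the exploratory step).
#' @param n_obs Number of observations; required when `x` is a covariance
#'   matrix, otherwise taken from `nrow(x)`.
#' @return Object of class `absolex_cfa`: list with `chi_square`, `df`,
#'   `p_value`, `gfi`, `cfi`, `nfi`, `chi_square_baseline`, `df_baseline`,
#'   `loadings` (standardized), `uniquenesses`, `converged`, `n_obs`.
#' @export
cfa_one_factor <- function(x, words, n_obs = NULL) {
  if (is.matrix(x) && isSymmetric(unname(x)) && !is.null(n_obs)) {
    S <- x[words, words]
    n <- n_obs
  } else {
    df <- as.data.frame(x)
    miss <- setdiff(words, names(df))
    if (length(miss) > 0L) {
      stop("words not in matrix: ", paste(miss, collapse = ", "))
    }
    m <- as.matrix(df[words])
    S <- stats::cov(m)
    n <- if (is.null(n_obs)) nrow(m) else n_obs
  }
  p <- length(words)
  if (p < 3L) stop("a one-factor model needs >= 3 indicators")
  if (n <= p) stop("need more observations than indicators")
  ldetS <- determinant(S, logarithm = TRUE)$modulus
  if (!is.finite(ldetS)) stop("singular sample covariance matrix")

  fml <- function(par) {
    lam <- par[1:p]
    psi <- exp(par[(p + 1):(2 * p)])
    Sig <- tcrossprod(lam) + diag(psi, p)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ldet <- 2 * sum(log(diag(ch)))
    tr <- sum(diag(chol2inv(ch) %*% S))
    as.numeric(ldet + tr - ldetS - p)
  }
  e <- eigen(S, symmetric = TRUE)
  lam0 <- e$vectors[, 1] * sqrt(max(e$values[1], 1e-8))
  psi0 <- pmax(diag(S) - lam0^2, 0.05 * diag(S))
  opt <- stats::optim(c(lam0, log(psi0)), fml, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-12))
  converged <- opt$convergence == 0 && opt$value < 1e9
  if (!converged) {
    return(structure(list(chi_square = NA_real_, df = NA_real_,
                          p_value = NA_real_, gfi = NA_real_, cfi = NA_real_,
                          nfi = NA_real_, chi_square_baseline = NA_real_,
                          df_baseline = NA_real_, loadings = NULL,
                          uniquenesses = NULL, converged = FALSE, n_obs = n),
                     class = "absolex_cfa"))
  }
  lam <- opt$par[1:p]
  psi <- exp(opt$par[(p + 1):(2 * p)])
  if (lam[1] < 0) lam <- -lam
  Sig <- tcrossprod(lam) + diag(psi, p)

  chi2 <- (n - 1) * opt$value
  df_model <- p * (p + 1) / 2 - 2 * p
  chi2_b <- (n - 1) * as.numeric(sum(log(diag(S))) - ldetS)
  df_b <- p * (p + 1) / 2 - p

  W <- solve(Sig) %*% S
  gfi <- 1 - sum(diag((W - diag(p)) %*% (W - diag(p)))) / sum(diag(W %*% W))
  cfi <- 1 - max(chi2 - df_model, 0) / max(chi2_b - df_b, chi2 - df_model, 0)
  nfi <- (chi2_b - chi2) / chi2_b
  clip01 <- function(v) min(max(v, 0), 1)

  sdv <- sqrt(diag(S))
  structure(list(chi_square = chi2, df = df_model,
                 p_value = stats::pchisq(chi2, df_model, lower.tail = FALSE),
                 gfi = gfi, cfi = clip01(cfi), nfi = clip01(nfi),
                 chi_square_baseline = chi2_b, df_baseline = df_b,
                 loadings = stats::setNames(lam / sdv, words),
                 uniquenesses = stats::setNames(psi / diag(S), words),
                 converged = TRUE, n_obs = n),
            class = "absolex_cfa")
}

#' @export
print.absolex_cfa <- function(x, ...) {
  if (!x$converged) {
    cat("<one-factor CFA: did not converge>\n")
    return(invisible(x))
  }
  cat(sprintf("<one-factor CFA: chi-square(%d) = %.3f, p = %.3g, GFI = %.3f, CFI = %.3f, NFI = %.3f>\n",
              x$df, x$chi_square, x$p_value, x$gfi, x$cfi, x$nfi))
  invisible(x)
}
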