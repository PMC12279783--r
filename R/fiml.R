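## Two-group FIML machinery shared by the Cholesky and RI-CLPM fitters.
##
## Pairs are grouped by (zygosity [, sex pair]) and missing-data pattern;
## within a pattern the log-likelihood depends on the data only through the
## pattern's count, mean vector and ML scatter matrix, so each likelihood
## evaluation is O(p^3) per pattern regardless of sample size.  The compiled
## kernels in src/ consume these pattern statistics.

## Decompose rows of Y (n x p, NAs allowed) into missingness patterns.
## Returns a list of list(n, idx, ybar, S): idx = observed column indices,
## S = ML covariance of observed sub-vectors about their own mean.
fiml_pattern_stats <- function(Y) {
  if (nrow(Y) == 0L) return(list())
  obs <- !is.na(Y)
  key <- apply(obs, 1L, function(r) paste(as.integer(r), collapse = ""))
  out <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    idx <- which(obs[rows[1L], ])
    if (length(idx) == 0L) next
    Yo <- Y[rows, idx, drop = FALSE]
    ybar <- colMeans(Yo)
    Yc <- sweep(Yo, 2L, ybar)
    out[[length(out) + 1L]] <- list(n = length(rows), idx = idx, ybar = ybar,
                                    S = crossprod(Yc) / length(rows))
  }
  out
}

## -2 log-likelihood of pattern stats under N(mu, Sigma) (R reference path;
## the compiled kernels reimplement this and are cross-checked against it)
fiml_neg2ll_stats <- function(stats, mu, Sigma) {
  val <- 0
  for (p in stats) {
    So <- Sigma[p$idx, p$idx, drop = FALSE]
    R <- chol(So)
    d <- p$ybar - mu[p$idx]
    M <- p$S + tcrossprod(d)
    val <- val + p$n * (length(p$idx) * log(2 * pi) +
                          2 * sum(log(diag(R))) +
                          sum(diag(chol2inv(R) %*% M)))
  }
  val
}

#' Multivariate-normal -2 log-likelihood with missing data
#'
#' Brute-force per-row evaluation: each row contributes the density of its
#' observed sub-vector.  Used as the independent oracle for the compiled
#' FIML kernels.
#'
#' @param Y numeric matrix (rows = units), `NA` = missing.
#' @param mu mean vector.
#' @param Sigma covariance matrix.
#' @return the -2 log-likelihood (a scalar).
#' @export
mvn_neg2ll <- function(Y, mu, Sigma) {
  val <- 0
  for (i in seq_len(nrow(Y))) {
    idx <- which(!is.na(Y[i, ]))
    if (length(idx) == 0L) next
    So <- Sigma[idx, idx, drop = FALSE]
    R <- chol(So)
    d <- Y[i, idx] - mu[idx]
    z <- backsolve(R, d, transpose = TRUE)
    val <- val + length(idx) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2)
  }
  val
}

## central finite-difference gradient
fd_grad <- function(fn, x, h = 1e-6) {
  g <- numeric(length(x))
  for (j in seq_along(x)) {
    hj <- h * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + hj
    xm <- x; xm[j] <- x[j] - hj
    g[j] <- (fn(xp) - fn(xm)) / (2 * hj)
  }
  g
}

## minimize fn over free parameters with BFGS, multi-start; `starts` is a
## list of full-length start vectors; `fixed` a named numeric vector of
## parameter index -> fixed value
fiml_optimize <- function(fn, starts, fixed = numeric(), reltol = 1e-12,
                          maxit = 2000L) {
  npar <- length(starts[[1L]])
  fix_idx <- as.integer(names(fixed))
  free_idx <- setdiff(seq_len(npar), fix_idx)
  embed <- function(xf) {
    x <- numeric(npar)
    x[free_idx] <- xf
    x[fix_idx] <- unname(fixed)
    x
  }
  fnf <- function(xf) {
    v <- tryCatch(fn(embed(xf)), error = function(e) NA_real_)
    if (!is.finite(v)) 1e12 else v
  }
  grf <- function(xf) fd_grad(fnf, xf)
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(s[free_idx], fnf, grf, method = "BFGS",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("optimization failed from every start")
  gnorm <- sqrt(sum(grf(best$par)^2))
  list(par = embed(best$par), value = best$value,
       converged = best$convergence == 0 || gnorm < 1e-2 * (1 + abs(best$value)),
       gradient_norm = gnorm, counts = best$counts, free_idx = free_idx)
}

## jitter a start vector reproducibly (used for multi-start)
jitter_starts <- function(start, n_starts, scale = 0.2) {
  c(list(start), lapply(seq_len(max(0L, n_starts - 1L)), function(i) {
    start + scale * stats::rnorm(length(start))
  }))
}

## EM algorithm for the saturated MVN model with missing data (one group).
## Returns list(mu, Sigma, neg2ll).  Complete data short-circuits to the
## closed form.
mvn_saturated <- function(Y, max_iter = 500L, tol = 1e-10) {
  p <- ncol(Y)
  cc <- stats::complete.cases(Y)
  if (all(cc)) {
    mu <- colMeans(Y)
    S <- crossprod(sweep(Y, 2L, mu)) / nrow(Y)
    return(list(mu = mu, Sigma = S,
                neg2ll = nrow(Y) * (p * log(2 * pi) +
                                      determinant(S)$modulus[1] + p)))
  }
  mu <- colMeans(Y, na.rm = TRUE)
  v <- apply(Y, 2L, stats::var, na.rm = TRUE)
  S <- diag(ifelse(is.finite(v) & v > 0, v, 1), p)
  stats <- fiml_pattern_stats(Y)
  ll_old <- Inf
  for (it in seq_len(max_iter)) {
    ES <- matrix(0, p, p); Em <- numeric(p); n <- 0L
    for (pt in stats) {
      o <- pt$idx; ms <- setdiff(seq_len(p), o)
      Soo_inv <- solve(S[o, o, drop = FALSE])
      ## per-pattern sufficient statistics of completed data
      yo <- pt$ybar
      Ey <- numeric(p); Ey[o] <- yo
      Eyy <- matrix(0, p, p)
      Eyy[o, o] <- pt$S + tcrossprod(yo)
      if (length(ms)) {
        B <- S[ms, o, drop = FALSE] %*% Soo_inv
        mu_m <- mu[ms] + B %*% (yo - mu[o])
        Ey[ms] <- mu_m
        Cov_mm <- S[ms, ms, drop = FALSE] - B %*% S[o, ms, drop = FALSE]
        ## E[y_m y_o'] = mu_m yo' + B * S_oo(pattern scatter)
        Eyy[ms, o] <- mu_m %*% t(yo) + B %*% pt$S
        Eyy[o, ms] <- t(Eyy[ms, o, drop = FALSE])
        Eyy[ms, ms] <- Cov_mm + B %*% pt$S %*% t(B) + tcrossprod(mu_m)
      }
      Em <- Em + pt$n * Ey
      ES <- ES + pt$n * Eyy
      n <- n + pt$n
    }
    mu <- Em / n
    S <- ES / n - tcrossprod(mu)
    S <- (S + t(S)) / 2
    ll <- fiml_neg2ll_stats(stats, mu, S)
    if (abs(ll_old - ll) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(mu = mu, Sigma = S, neg2ll = fiml_neg2ll_stats(stats, mu, S))
}

## independence-model (baseline) -2lnL for one group: per-variable ML mean
## and variance over observed values (the likelihood factorizes)
mvn_independence <- function(Y) {
  val <- 0
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]; y <- y[!is.na(y)]
    n <- length(y)
    if (n == 0L) next
    v <- sum((y - mean(y))^2) / n
    val <- val + n * (log(2 * pi) + log(v) + 1)
  }
  val
}
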