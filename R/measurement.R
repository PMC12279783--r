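## General-factor measurement stage: FCS imputation, one-factor models with
## cross-wave loading-equality constraints, regression factor scores, and
## cross-wave composite aggregation.

#' Chained-equation imputation of missing scores
#'
#' Fully conditional specification at the individual level: each variable
#' with missing entries is regressed (ridge-stabilized OLS) on all other
#' trait-wave variables of the same twin, missing cells are replaced by the
#' linear prediction plus a residual draw, and the system is swept
#' `n_iterations` times.  This is repeated for `n_imputations` chains with
#' different streams and the cell-wise mean of the completed datasets is
#' returned, matching the downstream use of mean scores as input variables.
#'
#' @param data a [twin_panel()].
#' @param n_imputations number of imputation chains (default 10).
#' @param n_iterations FCS sweeps per chain (default 10).
#' @param seed integer seed.
#' @return the completed panel (no missing score cells).
#' @export
impute_fcs <- function(data, n_imputations = 10L, n_iterations = 10L, seed) {
  X <- individual_matrix(data)
  V <- ncol(X)
  obs <- !is.na(X)
  none <- colSums(obs) == 0L
  if (any(none))
    stop("impute_fcs: variable(s) with zero observed values: ",
         paste(colnames(X)[none], collapse = ", "))
  has_miss <- which(colSums(!obs) > 0L)
  if (length(has_miss) == 0L) return(data)
  acc <- matrix(0, nrow(X), V)
  for (imp in seq_len(n_imputations)) {
    set.seed(seed + imp)
    Xc <- X
    for (j in seq_len(V)) {
      mj <- !obs[, j]
      if (any(mj))
        Xc[mj, j] <- sample(X[obs[, j], j], sum(mj), replace = TRUE)
    }
    for (it in seq_len(n_iterations)) {
      for (j in has_miss) {
        mj <- !obs[, j]
        Z <- cbind(1, Xc[, -j, drop = FALSE])
        zo <- Z[!mj, , drop = FALSE]
        yo <- X[!mj, j]
        G <- crossprod(zo)
        ridge <- 1e-6 * mean(diag(G))
        beta <- solve(G + diag(ridge, ncol(Z)), crossprod(zo, yo))
        res <- yo - zo %*% beta
        sig <- sqrt(sum(res^2) / max(length(yo) - ncol(Z), 1L))
        Xc[mj, j] <- Z[mj, , drop = FALSE] %*% beta +
          stats::rnorm(sum(mj), 0, sig)
      }
    }
    acc <- acc + Xc
  }
  set_individual_matrix(data, acc / n_imputations)
}

## ML discrepancy fit of the wave-constrained one-factor model on a sample
## covariance S (p = k * n_waves, columns wave-major).  Loadings equal across
## waves, uniquenesses free per wave, factor variances 1, factors correlated.
ml_onefactor_waves <- function(S, n, k, n_waves) {
  p <- k * n_waves
  stopifnot(nrow(S) == p)
  noff <- n_waves * (n_waves - 1L) / 2L
  loadmat <- function(lam) {
    L <- matrix(0, p, n_waves)
    for (w in seq_len(n_waves)) L[(w - 1L) * k + seq_len(k), w] <- lam
    L
  }
  phimat <- function(z) {
    Phi <- diag(n_waves)
    Phi[upper.tri(Phi)] <- tanh(z)
    Phi[lower.tri(Phi)] <- t(Phi)[lower.tri(Phi)]
    Phi
  }
  ## -2 log-likelihood up to the data-only constant (S may be singular for
  ## degenerate inputs, so log|S| is not subtracted)
  fn <- function(th) {
    lam <- th[seq_len(k)]
    psi <- exp(th[k + seq_len(p)])
    Phi <- phimat(th[k + p + seq_len(noff)])
    R <- tryCatch(chol(Phi), error = function(e) NULL)
    if (is.null(R)) return(1e12)
    L <- loadmat(lam)
    Sigma <- L %*% Phi %*% t(L) + diag(psi, p)
    Rs <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(Rs)) return(1e12)
    ldSig <- 2 * sum(log(diag(Rs)))
    tr <- sum(chol2inv(Rs) * S)
    n * (ldSig + tr)
  }
  ## principal-component start on the wave-averaged correlation block
  Ravg <- matrix(0, k, k)
  for (w in seq_len(n_waves)) {
    blk <- stats::cov2cor(S[(w - 1L) * k + seq_len(k),
                            (w - 1L) * k + seq_len(k), drop = FALSE])
    Ravg <- Ravg + blk / n_waves
  }
  ev <- eigen(Ravg, symmetric = TRUE)
  lam0 <- ev$vectors[, 1L] * sqrt(max(ev$values[1L], 0.1))
  lam0 <- pmin(pmax(lam0, -0.95), 0.95)
  th0 <- c(lam0, log(pmax(rep(1 - lam0^2, n_waves), 0.05)),
           rep(atanh(0.5), noff))
  opt <- stats::optim(th0, fn, function(x) fd_grad(fn, x), method = "BFGS",
                      control = list(maxit = 2000L, reltol = 1e-12))
  lam <- opt$par[seq_len(k)]
  psi <- matrix(exp(opt$par[k + seq_len(p)]), k, n_waves)
  Phi <- phimat(opt$par[k + p + seq_len(noff)])
  L <- loadmat(lam)
  Sigma <- L %*% Phi %*% t(L) + diag(as.vector(psi), p)
  loglik <- -n / 2 * (p * log(2 * pi) +
                        determinant(Sigma)$modulus[1] +
                        sum(diag(solve(Sigma, S))))
  list(lambda = lam, psi = psi, Phi = Phi, Sigma = Sigma,
       discrepancy = opt$value, loglik = as.numeric(loglik),
       converged = opt$convergence == 0)
}

#' Fit a general factor with loadings constrained equal across waves
#'
#' Maximum-likelihood fit of a correlated three-factor model (one factor per
#' wave) over `k * n_waves` standardized indicators, with each indicator's
#' loading constrained equal across waves, uniquenesses free per wave and
#' factor variances fixed at 1.  Indicators are z-scored over all pooled
#' individuals before fitting (the constituent scales have heterogeneous
#' ranges).  The factor sign is oriented so the anchor indicator loads
#' positively.
#'
#' @param data a [twin_panel()] containing the indicator scores (impute
#'   first if cells are missing: the covariance is computed from complete
#'   individuals).
#' @param spec a [trait_spec()] naming the indicators and the anchor.
#' @return an object of class `general_factor_fit`: `lambda` (named,
#'   shared across waves), `psi` (k x n_waves uniquenesses), `Phi`
#'   (inter-wave factor correlations), `explained_variance` (mean over
#'   indicators and waves of `lambda^2 / (lambda^2 + psi)`), `loglik`,
#'   `n_params`, and the standardization constants used.
#' @export
fit_general_factor <- function(data, spec) {
  stopifnot(inherits(spec, "trait_spec"))
  waves <- tp_waves(data)
  k <- length(spec$indicators)
  vars <- tp_vars(spec$indicators, waves)
  X <- individual_matrix(data)[, vars, drop = FALSE]
  cc <- stats::complete.cases(X)
  if (sum(cc) < k * length(waves) + 10L)
    stop("fit_general_factor: too few complete individuals")
  Xc <- X[cc, , drop = FALSE]
  center <- colMeans(Xc)
  scale <- apply(Xc, 2L, stats::sd)
  if (any(scale <= 0)) stop("fit_general_factor: constant indicator")
  Z <- sweep(sweep(Xc, 2L, center), 2L, scale, "/")
  n <- nrow(Z)
  S <- crossprod(Z) / n     # ML covariance of standardized indicators
  res <- ml_onefactor_waves(S, n, k, length(waves))
  if (!res$converged)
    warning("fit_general_factor: optimizer reported non-convergence")
  if (any(res$psi < 1e-4))
    warning("fit_general_factor: uniqueness bounded near 0 (Heywood case)")
  names(res$lambda) <- spec$indicators
  a <- match(spec$anchor, spec$indicators)
  if (res$lambda[a] < 0) res$lambda <- -res$lambda
  expl <- mean(res$lambda^2 / (res$lambda^2 + res$psi))
  structure(list(
    lambda = res$lambda, psi = res$psi, Phi = res$Phi,
    explained_variance = expl, loglik = res$loglik,
    discrepancy = res$discrepancy,
    n_params = k + k * length(waves) + length(waves) * (length(waves) - 1L) / 2L,
    n = n, center = center, scale = scale, spec = spec, waves = waves),
    class = "general_factor_fit")
}

#' @export
print.general_factor_fit <- function(x, ...) {
  cat("General factor of ", x$spec$name, " (one factor per wave, loadings ",
      "equal across waves)\n", sep = "")
  cat("  n = ", x$n, " individuals, explained variance = ",
      round(100 * x$explained_variance), "%\n", sep = "")
  print(round(x$lambda, 2))
  cat("  inter-wave factor correlations:\n")
  print(round(x$Phi, 2))
  invisible(x)
}

#' @export
coef.general_factor_fit <- function(object, ...) object$lambda

#' Regression (Thurstone) factor scores
#'
#' Computes joint regression scores for the wave factors,
#' `f = Phi L' Sigma^{-1} x`, using the model-implied covariance of the
#' standardized indicators; for individuals with missing indicators the
#' observed sub-vector's implied covariance is used.  A wave's score is
#' missing when all of that wave's indicators are missing.
#'
#' @param fit a `general_factor_fit`.
#' @param data a [twin_panel()] containing the indicator columns.
#' @return a [twin_panel()] with one trait (the factor name) at the fitted
#'   waves.
#' @export
factor_scores <- function(fit, data) {
  waves <- fit$waves
  k <- length(fit$spec$indicators)
  vars <- tp_vars(fit$spec$indicators, waves)
  L <- matrix(0, k * length(waves), length(waves))
  for (w in seq_along(waves)) L[(w - 1L) * k + seq_len(k), w] <- fit$lambda
  Sigma <- L %*% fit$Phi %*% t(L) + diag(as.vector(fit$psi), nrow(L))
  CovFX <- fit$Phi %*% t(L)    # n_waves x p
  score_block <- function(M) {
    Z <- sweep(sweep(M, 2L, fit$center), 2L, fit$scale, "/")
    out <- matrix(NA_real_, nrow(Z), length(waves))
    key <- apply(!is.na(Z), 1L, function(r) paste(as.integer(r), collapse = ""))
    for (kk in unique(key)) {
      rows <- which(key == kk)
      idx <- which(!is.na(Z[rows[1L], ]))
      if (length(idx) == 0L) next
      Wt <- CovFX[, idx, drop = FALSE] %*%
        solve(Sigma[idx, idx, drop = FALSE])
      out[rows, ] <- Z[rows, idx, drop = FALSE] %*% t(Wt)
      ## a wave with no observed indicators gets no score
      for (w in seq_along(waves)) {
        widx <- (w - 1L) * k + seq_len(k)
        if (!any(widx %in% idx)) out[rows, w] <- NA_real_
      }
    }
    out
  }
  res <- data[, c("pair_id", "zygosity", "sex_t1", "sex_t2")]
  for (tw in c("t1", "t2")) {
    M <- as.matrix(data[, paste0(vars, "_", tw), drop = FALSE])
    storage.mode(M) <- "double"
    sc <- score_block(M)
    for (w in seq_along(waves))
      res[[paste0(fit$spec$name, "_", waves[w], "_", tw)]] <- sc[, w]
  }
  twin_panel(res, traits = fit$spec$name, waves = waves)
}

## plain one-factor ML fit on a small covariance matrix (free loadings)
ml_factor1 <- function(S, n) {
  p <- nrow(S)
  fn <- function(th) {
    lam <- th[seq_len(p)]; psi <- exp(th[p + seq_len(p)])
    Sigma <- tcrossprod(lam) + diag(psi, p)
    R <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(R)) return(1e12)
    n * (2 * sum(log(diag(R))) + sum(chol2inv(R) * S))
  }
  ev <- eigen(stats::cov2cor(S), symmetric = TRUE)
  d <- sqrt(diag(S))
  lam0 <- ev$vectors[, 1L] * sqrt(max(ev$values[1L], 0.2)) * d
  th0 <- c(lam0, log(pmax(diag(S) - lam0^2, 0.05 * diag(S))))
  opt <- stats::optim(th0, fn, function(x) fd_grad(fn, x), method = "BFGS",
                      control = list(maxit = 1000L, reltol = 1e-12))
  lam <- opt$par[seq_len(p)]
  if (sum(lam) < 0) lam <- -lam
  list(lambda = lam, psi = exp(opt$par[p + seq_len(p)]),
       converged = opt$convergence == 0)
}

#' Aggregate wave scores into a cross-wave composite factor
#'
#' For each trait, fits a one-factor model to the trait's scores at the
#' available waves and returns the regression factor score as a composite
#' capturing the variance shared across waves (time-invariant stability).
#' Individuals with fewer than two observed waves get a missing composite.
#' Traits whose wave scores are essentially uncorrelated (all standardized
#' loadings below 0.2) are flagged with a warning as degenerate.
#'
#' @param scores a [twin_panel()] of factor scores.
#' @param traits traits to aggregate (default: all).
#' @return a [twin_panel()] with the same trait names at a single wave
#'   (wave 1); the per-trait factor fits are attached as attribute
#'   `"composite_fits"`.
#' @export
aggregate_composite <- function(scores, traits = tp_traits(scores)) {
  waves <- tp_waves(scores)
  stopifnot(length(waves) >= 2L)
  res <- scores[, c("pair_id", "zygosity", "sex_t1", "sex_t2")]
  fits <- list()
  for (trait in traits) {
    vars <- paste0(trait, "_", waves)
    X <- individual_matrix(scores)[, vars, drop = FALSE]
    cc <- stats::complete.cases(X)
    S <- crossprod(sweep(X[cc, , drop = FALSE], 2L,
                         colMeans(X[cc, , drop = FALSE]))) / sum(cc)
    f1 <- ml_factor1(S, sum(cc))
    R <- stats::cov2cor(S)
    if (max(abs(R[upper.tri(R)])) < 0.1)
      warning("aggregate_composite: degenerate composite for ", trait,
              " (wave scores nearly independent)")
    fits[[trait]] <- f1
    Sigma <- tcrossprod(f1$lambda) + diag(f1$psi, length(vars))
    ctr <- colMeans(X, na.rm = TRUE)
    comp_block <- function(M) {
      Z <- sweep(M, 2L, ctr)
      out <- rep(NA_real_, nrow(Z))
      key <- apply(!is.na(Z), 1L, function(r) paste(as.integer(r), collapse = ""))
      for (kk in unique(key)) {
        rows <- which(key == kk)
        idx <- which(!is.na(Z[rows[1L], ]))
        if (length(idx) < 2L) next
        Wt <- f1$lambda[idx] %*% solve(Sigma[idx, idx, drop = FALSE])
        out[rows] <- Z[rows, idx, drop = FALSE] %*% t(Wt)
      }
      out
    }
    n <- nrow(scores)
    for (tw in c("t1", "t2")) {
      M <- as.matrix(scores[, paste0(vars, "_", tw), drop = FALSE])
      storage.mode(M) <- "double"
      res[[paste0(trait, "_1_", tw)]] <- comp_block(M)
    }
  }
  out <- twin_panel(res, traits = traits, waves = 1L)
  attr(out, "composite_fits") <- fits
  out
}
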