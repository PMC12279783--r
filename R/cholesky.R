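## Multivariate Cholesky ACE/AE twin model by two-group FIML.

#' Model-implied pair moments of a Cholesky twin model
#'
#' Within-twin covariance `A + C + E`; cross-twin covariance `A + C` for MZ
#' pairs or `0.5 A + C` for DZ pairs; sex-specific means.
#'
#' @param params a [cholesky_params()] object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param sex_pair length-2 vector of twin sexes (0/1 or `"male"`/`"female"`).
#' @return list with `mean` (length 2m) and `Sigma` (2m x 2m).
#' @export
implied_pair_moments <- function(params, zygosity = c("MZ", "DZ"),
                                 sex_pair = c(0, 0)) {
  zygosity <- match.arg(zygosity)
  if (is.character(sex_pair))
    sex_pair <- match(sex_pair, c("male", "female")) - 1L
  r <- if (zygosity == "MZ") 1 else 0.5
  A <- tcrossprod(params$a); C <- tcrossprod(params$c)
  E <- tcrossprod(params$e)
  within <- A + C + E
  cross <- r * A + C
  Sigma <- rbind(cbind(within, cross), cbind(t(cross), within))
  vars <- paste0(rep(params$variables, 2L), "_t", rep(1:2, each = nrow(A)))
  dimnames(Sigma) <- list(vars, vars)
  mu <- c(params$means[, sex_pair[1L] + 1L], params$means[, sex_pair[2L] + 1L])
  list(mean = mu, Sigma = Sigma)
}

cholesky_pack <- function(params, ace) {
  m <- nrow(params$a)
  lt <- lower.tri(params$a, diag = TRUE)
  th <- params$a[lt]
  if (ace) th <- c(th, params$c[lt])
  c(th, params$e[lt], params$means[, 1L], params$means[, 2L])
}

cholesky_unpack <- function(theta, m, ace, variables) {
  nlt <- m * (m + 1L) / 2L
  lt <- lower.tri(matrix(0, m, m), diag = TRUE)
  take <- function(off) {
    M <- matrix(0, m, m); M[lt] <- theta[off + seq_len(nlt)]; M
  }
  a <- take(0L)
  c_ <- if (ace) take(nlt) else NULL
  e <- take(if (ace) 2L * nlt else nlt)
  moff <- (if (ace) 3L else 2L) * nlt
  means <- cbind(male = theta[moff + seq_len(m)],
                 female = theta[moff + m + seq_len(m)])
  cholesky_params(a = a, e = e, c = c_, means = means, variables = variables)
}

## group the pair data by zygosity and sex combination, with pattern stats
cholesky_groups <- function(data, variables) {
  vr <- parse_variables(variables)
  keep <- !is.na(data$sex_t1) & !is.na(data$sex_t2)
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " pair(s) with missing sex")
    data <- data[keep, , drop = FALSE]
  }
  groups <- list()
  for (zyg in c("MZ", "DZ")) {
    sub <- data[data$zygosity == zyg, , drop = FALSE]
    for (s1 in 0:1) for (s2 in 0:1) {
      rows <- sub$sex_t1 == s1 & sub$sex_t2 == s2
      if (!any(rows)) next
      g <- sub[rows, , drop = FALSE]
      Y <- cbind(as.matrix(g[, paste0(variables, "_t1"), drop = FALSE]),
                 as.matrix(g[, paste0(variables, "_t2"), drop = FALSE]))
      storage.mode(Y) <- "double"
      st <- fiml_pattern_stats(Y)
      if (!length(st)) next
      groups[[length(groups) + 1L]] <-
        list(r = if (zyg == "MZ") 1 else 0.5, s1 = s1, s2 = s2,
             zygosity = zyg, stats = st, n = nrow(Y), Y = Y)
    }
  }
  groups
}

## Falconer-style moment starting values
cholesky_start <- function(data, variables, ace) {
  m <- length(variables)
  X1 <- as.matrix(data[, paste0(variables, "_t1"), drop = FALSE])
  X2 <- as.matrix(data[, paste0(variables, "_t2"), drop = FALSE])
  storage.mode(X1) <- storage.mode(X2) <- "double"
  S <- stats::cov(rbind(X1, X2), use = "pairwise.complete.obs")
  ct <- function(zyg) {
    i <- data$zygosity == zyg
    C <- stats::cov(rbind(X1[i, , drop = FALSE], X2[i, , drop = FALSE]),
                    rbind(X2[i, , drop = FALSE], X1[i, , drop = FALSE]),
                    use = "pairwise.complete.obs")
    C[!is.finite(C)] <- 0
    (C + t(C)) / 2
  }
  Cmz <- ct("MZ"); Cdz <- ct("DZ")
  floor_eig <- 0.05 * mean(diag(S))
  if (ace) {
    A0 <- make_pd(2 * (Cmz - Cdz), floor_eig)
    C0 <- make_pd(2 * Cdz - Cmz, floor_eig)
  } else {
    A0 <- make_pd((Cmz + 2 * Cdz) / 2, floor_eig)
    C0 <- NULL
  }
  E0 <- make_pd(S - (if (ace) A0 + C0 else A0), floor_eig)
  sex <- c(data$sex_t1, data$sex_t2)
  Xall <- rbind(X1, X2)
  means <- vapply(0:1, function(s)
    colMeans(Xall[sex == s, , drop = FALSE], na.rm = TRUE), numeric(m))
  means <- matrix(means, m, 2L)
  means[!is.finite(means)] <- 0
  p0 <- cholesky_params(a = t(chol(A0)), e = t(chol(E0)),
                        c = if (ace) t(chol(C0)) else NULL,
                        means = means, variables = variables)
  cholesky_pack(p0, ace)
}

#' Fit a multivariate Cholesky ACE or AE twin model by FIML
#'
#' Maximizes the two-group (MZ/DZ) multivariate-normal likelihood over
#' lower-triangular genetic and environmental path matrices, with separate
#' means for males and females.  Pairs with missing entries contribute via
#' their observed sub-vectors.  The AE model constrains all shared-environment
#' paths to zero.  Starting values come from Falconer-style moment estimates;
#' additional jittered starts guard against local optima.
#'
#' @param data a [twin_panel()] with both zygosity groups.
#' @param variables character vector (length m <= 6) of `<trait>_<wave>`
#'   variable labels to model.
#' @param model `"ACE"` or `"AE"`.
#' @param n_starts number of optimizer starts (default 5).
#' @param reltol optimizer relative tolerance.
#' @return an object of class `cholesky_fit`: `params` ([cholesky_params()]
#'   estimates), `minus2lnL`, `n_params`, `AIC`, `BIC` (N = number of twin
#'   pairs, the independent sampling units), `converged`, `N`, `model`.
#' @export
fit_cholesky <- function(data, variables, model = c("ACE", "AE"),
                         n_starts = 5L, reltol = 1e-12) {
  model <- match.arg(model)
  ace <- model == "ACE"
  m <- length(variables)
  stopifnot(m >= 1L, m <= 6L)
  if (!all(c("MZ", "DZ") %in% data$zygosity))
    stop("fit_cholesky: both zygosity groups are required (A and C are not ",
         "separable from one group)")
  groups <- cholesky_groups(data, variables)
  cgroups <- lapply(groups, function(g) g[c("r", "s1", "s2", "stats")])
  fn <- function(th) cholesky_neg2ll_cpp(th, m, ace, cgroups)
  start <- cholesky_start(data, variables, ace)
  starts <- with_preserved_seed(2L, jitter_starts(start, n_starts, scale = 0.1))
  opt <- fiml_optimize(fn, starts, reltol = reltol)
  n_par <- length(start)
  N <- sum(vapply(groups, `[[`, 0, "n"))
  params <- cholesky_unpack(opt$par, m, ace, variables)
  structure(list(
    params = params, theta = opt$par, minus2lnL = opt$value,
    n_params = n_par, AIC = opt$value + 2 * n_par,
    BIC = opt$value + n_par * log(N),
    converged = opt$converged, gradient_norm = opt$gradient_norm,
    N = N, model = model, variables = variables,
    fingerprint = data_fingerprint(do.call(rbind, lapply(groups, `[[`, "Y")))),
    class = "cholesky_fit")
}

#' @export
print.cholesky_fit <- function(x, ...) {
  cat("Cholesky ", x$model, " twin model (", length(x$variables),
      " variables, ", x$N, " pairs)\n", sep = "")
  cat("  -2lnL = ", format(x$minus2lnL, digits = 10), ", ", x$n_params,
      " parameters, AIC = ", round(x$AIC, 2), ", BIC = ", round(x$BIC, 2),
      "\n", sep = "")
  if (!x$converged) cat("  WARNING: optimizer did not converge cleanly\n")
  print(variance_components(x))
  invisible(x)
}

#' @export
logLik.cholesky_fit <- function(object, ...) {
  structure(-object$minus2lnL / 2, df = object$n_params,
            nobs = object$N, class = "logLik")
}

#' @export
coef.cholesky_fit <- function(object, ...) object$theta

#' @export
simulate.cholesky_fit <- function(object, nsim = 1, seed = 1, n_mz = 577L,
                                  n_dz = 961L, ...) {
  out <- lapply(seq_len(nsim), function(i)
    simulate_cholesky_panel(object$params, n_mz, n_dz, seed = seed + i - 1L))
  if (nsim == 1L) out[[1L]] else out
}

#' Compare twin-model fits by information criteria
#'
#' @param ... two or more fitted models (`cholesky_fit` or `riclpm_fit`) on
#'   the same data and variables.
#' @return data frame with -2lnL, parameter counts, AIC, BIC, differences to
#'   the best model, and which model each criterion prefers.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1L]]) && !inherits(fits[[1L]], c("cholesky_fit", "riclpm_fit")))
    fits <- fits[[1L]]
  stopifnot(length(fits) >= 2L)
  fps <- lapply(fits, `[[`, "fingerprint")
  if (!all(vapply(fps, function(f) isTRUE(all.equal(f, fps[[1L]])), TRUE)))
    stop("compare_models: fits are not on identical data")
  nm <- names(fits)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- vapply(fits, function(f)
      if (!is.null(f$model)) f$model else class(f)[1L], "")
  tab <- data.frame(
    model = nm,
    minus2lnL = vapply(fits, `[[`, 0, "minus2lnL"),
    n_params = vapply(fits, `[[`, 0L, "n_params"),
    AIC = vapply(fits, `[[`, 0, "AIC"),
    BIC = vapply(fits, `[[`, 0, "BIC"),
    stringsAsFactors = FALSE)
  tab$dAIC <- tab$AIC - min(tab$AIC)
  tab$dBIC <- tab$BIC - min(tab$BIC)
  tab$preferred_AIC <- tab$dAIC == 0
  tab$preferred_BIC <- tab$dBIC == 0
  tab
}

#' Standardized variance components of a Cholesky fit
#'
#' Per variable: standardized a2/c2/e2 shares; genetic, shared- and
#' non-shared-environmental correlation matrices; and, for bivariate fits,
#' the percentage of each trait's genetic (and E) variance shared with the
#' other trait.  The default `"rA2"` convention computes shared percentage as
#' `100 * rA^2`, symmetric in the two traits; the `"path"` convention uses
#' the order-dependent Cholesky path shares `100 * a21^2 / (a21^2 + a22^2)`
#' (identical for the second-ordered trait, slightly asymmetric overall).
#'
#' @param fit a converged `cholesky_fit`.
#' @param shared_convention `"rA2"` (default) or `"path"`.
#' @return an object of class `variance_components`.
#' @export
variance_components <- function(fit, shared_convention = c("rA2", "path")) {
  shared_convention <- match.arg(shared_convention)
  p <- fit$params
  A <- tcrossprod(p$a); C <- tcrossprod(p$c); E <- tcrossprod(p$e)
  tot <- diag(A) + diag(C) + diag(E)
  if (any(tot <= 0)) stop("variance_components: zero total variance")
  safe_cor <- function(M) {
    d <- sqrt(pmax(diag(M), 1e-12))
    sweep(sweep(M, 1L, d, "/"), 2L, d, "/")
  }
  out <- list(
    variables = p$variables,
    a2 = diag(A) / tot, c2 = diag(C) / tot, e2 = diag(E) / tot,
    rA = safe_cor(A), rC = safe_cor(C), rE = safe_cor(E),
    model = fit$model)
  names(out$a2) <- names(out$c2) <- names(out$e2) <- p$variables
  if (length(p$variables) == 2L) {
    if (shared_convention == "rA2") {
      out$shared_pct_A <- stats::setNames(rep(100 * out$rA[1, 2]^2, 2L),
                                          p$variables)
      out$shared_pct_E <- stats::setNames(rep(100 * out$rE[1, 2]^2, 2L),
                                          p$variables)
    } else {
      shr <- function(L) {
        ## share of variance in each trait carried by the other trait's factor
        c(100 * L[1, 1]^2 / sum(L[1, ]^2), 100 * L[2, 1]^2 / sum(L[2, ]^2))
      }
      ## for trait 1 (first-ordered) the cross share uses the reversed order
      rev_idx <- 2:1
      a_rev <- t(chol(A[rev_idx, rev_idx]))
      e_rev <- t(chol(E[rev_idx, rev_idx]))
      out$shared_pct_A <- stats::setNames(
        c(shr(a_rev)[2L], shr(p$a)[2L]), p$variables)
      out$shared_pct_E <- stats::setNames(
        c(shr(e_rev)[2L], shr(p$e)[2L]), p$variables)
    }
  }
  class(out) <- "variance_components"
  out
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Standardized variance components (", x$model, ")\n", sep = "")
  tab <- cbind(a2 = x$a2, c2 = x$c2, e2 = x$e2)
  if (x$model == "AE") tab <- tab[, c("a2", "e2"), drop = FALSE]
  if (!is.null(x$shared_pct_A))
    tab <- cbind(tab, `%A shared` = x$shared_pct_A,
                 `%E shared` = x$shared_pct_E)
  print(round(tab, 3))
  if (length(x$variables) > 1L) {
    cat("  rA:\n"); print(round(x$rA, 3))
    if (x$model == "ACE") { cat("  rC:\n"); print(round(x$rC, 3)) }
    cat("  rE:\n"); print(round(x$rE, 3))
  }
  invisible(x)
}
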