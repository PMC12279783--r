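## Genetically informative random-intercept cross-lagged panel model.

## ---- parameter packing -----------------------------------------------------
## Unconstrained vector (38 entries): each 2x2 covariance block as
## (log v1, log v2, atanh r); B matrices row-major; means wave-major.

pack_cov2 <- function(S) {
  v1 <- max(S[1, 1], 1e-10); v2 <- max(S[2, 2], 1e-10)
  r <- S[1, 2] / sqrt(v1 * v2)
  r <- min(max(r, -0.999), 0.999)
  c(log(v1), log(v2), atanh(r))
}

unpack_cov2 <- function(x) {
  v1 <- exp(x[1]); v2 <- exp(x[2]); r <- tanh(x[3])
  sym2(v1, v2, r * sqrt(v1 * v2))
}

riclpm_theta_names <- function() {
  blk <- function(nm) paste0(nm, c("_logv1", "_logv2", "_z"))
  c(blk("VA_ri"), blk("VE_ri"),
    paste0("B1_", c("11", "12", "21", "22")),
    paste0("B2_", c("11", "12", "21", "22")),
    blk("SA_w1"), blk("SE_w1"), blk("SA_u2"), blk("SE_u2"),
    blk("SA_u3"), blk("SE_u3"),
    paste0("mu_", c("1_w1", "2_w1", "1_w2", "2_w2", "1_w3", "2_w3")))
}

riclpm_pack <- function(params) {
  th <- c(pack_cov2(params$VA_ri), pack_cov2(params$VE_ri),
          as.vector(t(params$B1)), as.vector(t(params$B2)),
          pack_cov2(params$SA_w1), pack_cov2(params$SE_w1),
          pack_cov2(params$SA_u2), pack_cov2(params$SE_u2),
          pack_cov2(params$SA_u3), pack_cov2(params$SE_u3),
          as.vector(params$mu))
  names(th) <- riclpm_theta_names()
  th
}

riclpm_unpack <- function(theta, traits = c("personality", "psychopathology")) {
  riclpm_params(
    VA_ri = unpack_cov2(theta[1:3]), VE_ri = unpack_cov2(theta[4:6]),
    B1 = matrix(theta[7:10], 2L, byrow = TRUE),
    B2 = matrix(theta[11:14], 2L, byrow = TRUE),
    SA_w1 = unpack_cov2(theta[15:17]), SE_w1 = unpack_cov2(theta[18:20]),
    SA_u2 = unpack_cov2(theta[21:23]), SE_u2 = unpack_cov2(theta[24:26]),
    SA_u3 = unpack_cov2(theta[27:29]), SE_u3 = unpack_cov2(theta[30:32]),
    mu = matrix(theta[33:38], 2L, 3L), sex_effect = c(0, 0), traits = traits)
}

## ---- implied moments -------------------------------------------------------

#' Model-implied pair moments of the biometric RI-CLPM
#'
#' Builds the 12-dimensional mean vector and covariance matrix of a twin
#' pair's observations (2 twins x 2 traits x 3 waves; variable order within a
#' twin is wave-major, trait-minor, matching [panel_matrix()]).  The
#' within-twin block is the random-intercept covariance plus the within-person
#' process covariance propagated through the path matrices; the cross-twin
#' block contains only the additive-genetic parts, scaled by 1 (MZ) or 0.5
#' (DZ), with A parts of the within-person process propagating through the
#' same dynamics as the E parts.  Sex effects are not part of the implied
#' moments (the fitted model consumes sex-residualized scores).
#'
#' @param params a [riclpm_params()] object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return list with `mean` (length 12) and `Sigma` (12 x 12).
#' @export
riclpm_implied_moments <- function(params, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  r <- if (zygosity == "MZ") 1 else 0.5
  lagc <- function(V1, U2, U3) {
    B1 <- params$B1; B2 <- params$B2
    V2 <- B1 %*% V1 %*% t(B1) + U2
    V3 <- B2 %*% V2 %*% t(B2) + U3
    C21 <- B1 %*% V1; C31 <- B2 %*% C21; C32 <- B2 %*% V2
    W <- matrix(0, 6L, 6L)
    W[1:2, 1:2] <- V1; W[3:4, 3:4] <- V2; W[5:6, 5:6] <- V3
    W[3:4, 1:2] <- C21; W[1:2, 3:4] <- t(C21)
    W[5:6, 1:2] <- C31; W[1:2, 5:6] <- t(C31)
    W[5:6, 3:4] <- C32; W[3:4, 5:6] <- t(C32)
    W
  }
  WA <- lagc(params$SA_w1, params$SA_u2, params$SA_u3)
  WE <- lagc(params$SE_w1, params$SE_u2, params$SE_u3)
  KA <- matrix(1, 3L, 3L) %x% params$VA_ri
  KE <- matrix(1, 3L, 3L) %x% params$VE_ri
  Sw <- KA + KE + WA + WE
  TA <- KA + WA
  Sigma <- rbind(cbind(Sw, r * TA), cbind(r * t(TA), Sw))
  vars <- tp_vars(params$traits, 1:3)
  dimnames(Sigma) <- list(paste0(rep(vars, 2), "_t", rep(1:2, each = 6)),
                          paste0(rep(vars, 2), "_t", rep(1:2, each = 6)))
  list(mean = rep(as.vector(params$mu), 2L), Sigma = Sigma)
}

## ---- fitting ---------------------------------------------------------------

## pair-level 12-column data matrix for one zygosity group
riclpm_pair_matrix <- function(data, traits, zygosity) {
  sub <- data[data$zygosity == zygosity, , drop = FALSE]
  sub <- twin_panel(sub, traits = tp_traits(data), waves = tp_waves(data))
  vars <- tp_vars(traits, tp_waves(data))
  m1 <- panel_matrix(sub, 1L)[, vars, drop = FALSE]
  m2 <- panel_matrix(sub, 2L)[, vars, drop = FALSE]
  cbind(m1, m2)
}

## moment-based starting values
riclpm_start <- function(data, traits) {
  X <- individual_matrix(data)[, tp_vars(traits, 1:3), drop = FALSE]
  S6 <- stats::cov(X, use = "pairwise.complete.obs")
  S6[!is.finite(S6)] <- 0
  blk <- function(t, s) S6[(2 * t - 1):(2 * t), (2 * s - 1):(2 * s)]
  symm <- function(m) (m + t(m)) / 2
  VRI <- 0.9 * symm(blk(1, 2) + blk(1, 3) + blk(2, 3)) / 3
  W <- lapply(1:3, function(t) make_pd(blk(t, t) - VRI, 0.05 * mean(diag(S6))))
  B1 <- (blk(2, 1) - VRI) %*% solve(W[[1]])
  B2 <- (blk(3, 2) - VRI) %*% solve(W[[2]])
  B1[abs(B1) > 0.9] <- sign(B1[abs(B1) > 0.9]) * 0.9
  B2[abs(B2) > 0.9] <- sign(B2[abs(B2) > 0.9]) * 0.9
  U2 <- make_pd(W[[2]] - B1 %*% W[[1]] %*% t(B1), 0.02 * mean(diag(S6)))
  U3 <- make_pd(W[[3]] - B2 %*% W[[2]] %*% t(B2), 0.02 * mean(diag(S6)))
  ## A fraction from the MZ/DZ cross-twin contrast
  ctc <- function(zyg) {
    Y <- riclpm_pair_matrix(data, traits, zyg)
    C <- stats::cov(cbind(rbind(Y[, 1:6], Y[, 7:12])),
                    rbind(Y[, 7:12], Y[, 1:6]), use = "pairwise.complete.obs")
    C[!is.finite(C)] <- 0
    C
  }
  Cmz <- ctc("MZ"); Cdz <- ctc("DZ")
  afrac <- stats::median(diag(2 * (Cmz - Cdz)) / pmax(diag(S6), 1e-8))
  afrac <- min(max(afrac, 0.15), 0.85)
  VRI <- make_pd(VRI, 0.02 * mean(diag(S6)))
  start_params <- riclpm_params(
    VA_ri = afrac * VRI, VE_ri = (1 - afrac) * VRI, B1 = B1, B2 = B2,
    SA_w1 = afrac * W[[1]], SE_w1 = (1 - afrac) * W[[1]],
    SA_u2 = afrac * U2, SE_u2 = (1 - afrac) * U2,
    SA_u3 = afrac * U3, SE_u3 = (1 - afrac) * U3,
    mu = matrix(colMeans(X, na.rm = TRUE), 2L, 3L), traits = traits)
  riclpm_pack(start_params)
}

## clamp a symmetric matrix's eigenvalues from below
make_pd <- function(m, min_eig) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  e$vectors %*% diag(pmax(e$values, min_eig), nrow(m)) %*% t(e$vectors)
}

#' Fit the biometric RI-CLPM by two-group FIML
#'
#' Estimates all parameters of the genetically informative random-intercept
#' cross-lagged panel model from pair-level data on two traits at three
#' waves: A/E covariances of the random intercepts, interval-specific
#' autoregressive and cross-lagged paths, A/E covariances of the wave-1
#' within-person component and of the wave-2/3 innovations, and one mean per
#' variable (common across twins, sexes and zygosity groups; inputs are
#' expected to be sex-residualized, see [residualize_on_sex()]).  Pairs with
#' missing entries contribute through their observed sub-vectors.
#' Optimization is multi-start quasi-Newton (BFGS) on an unconstrained
#' reparameterization (log variances, atanh correlations).
#'
#' @param data a [twin_panel()] with both zygosity groups.
#' @param traits the two traits to model (default: the panel's traits).
#' @param fixed named numeric vector fixing unconstrained parameters by
#'   index (used internally for cross-lag tests).
#' @param n_starts number of jittered starts beyond the moment-based one.
#' @param start optional full start vector (overrides the moment heuristic).
#' @param reltol optimizer relative tolerance.
#' @return an object of class `riclpm_fit` with components `params`
#'   ([riclpm_params()] estimates), `minus2lnL`, `n_params`, `AIC`, `BIC`
#'   (N = number of pairs), `converged`, `gradient_norm`, `N`, plus the
#'   pattern statistics needed by [fit_indices()] and [test_cross_lags()].
#' @references The phenotypic RI-CLPM follows Hamaker, Kuiper and Grasman's
#'   random-intercept formulation; the A/E extension assigns cross-twin
#'   correlations 1 (MZ) / 0.5 (DZ) to all additive-genetic streams.
#' @export
fit_riclpm <- function(data, traits = tp_traits(data), fixed = numeric(),
                       n_starts = 3L, start = NULL, reltol = 1e-12) {
  stopifnot(length(traits) == 2L, length(tp_waves(data)) == 3L)
  if (!all(c("MZ", "DZ") %in% data$zygosity))
    stop("fit_riclpm: both zygosity groups are required")
  Ymz <- riclpm_pair_matrix(data, traits, "MZ")
  Ydz <- riclpm_pair_matrix(data, traits, "DZ")
  stats_mz <- fiml_pattern_stats(Ymz)
  stats_dz <- fiml_pattern_stats(Ydz)
  fn <- function(th) riclpm_neg2ll_cpp(th, stats_mz, stats_dz)
  if (is.null(start)) start <- riclpm_start(data, traits)
  starts <- with_preserved_seed(1L, jitter_starts(unname(start), n_starts))
  opt <- fiml_optimize(fn, starts, fixed = fixed, reltol = reltol)
  n_par <- 38L - length(fixed)
  N <- nrow(Ymz) + nrow(Ydz)
  params <- riclpm_unpack(opt$par, traits)
  structure(list(
    params = params, theta = stats::setNames(opt$par, riclpm_theta_names()),
    minus2lnL = opt$value, n_params = n_par,
    AIC = opt$value + 2 * n_par, BIC = opt$value + n_par * log(N),
    converged = opt$converged, gradient_norm = opt$gradient_norm,
    N = N, n_mz = nrow(Ymz), n_dz = nrow(Ydz),
    stats = list(MZ = stats_mz, DZ = stats_dz),
    Y = list(MZ = Ymz, DZ = Ydz),
    fixed = fixed, traits = traits,
    fingerprint = data_fingerprint(rbind(Ymz, Ydz))),
    class = "riclpm_fit")
}

data_fingerprint <- function(Y) {
  c(n = nrow(Y), p = ncol(Y), obs = sum(!is.na(Y)),
    sum = round(sum(Y, na.rm = TRUE), 6))
}

with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

#' @export
print.riclpm_fit <- function(x, ...) {
  cat("Biometric RI-CLPM fit (", x$N, " pairs: ", x$n_mz, " MZ, ", x$n_dz,
      " DZ)\n", sep = "")
  cat("  -2lnL = ", format(x$minus2lnL, digits = 10), ", ", x$n_params,
      " parameters, AIC = ", round(x$AIC, 2), ", BIC = ", round(x$BIC, 2),
      "\n", sep = "")
  if (!x$converged) cat("  WARNING: optimizer did not converge cleanly\n")
  ds <- derived_stability(x)
  cat("  RI genetic correlation: ", round(ds$rA_ri, 3),
      "   RI E correlation: ", round(ds$rE_ri, 3), "\n", sep = "")
  cat("  A share of RI variance: ",
      paste0(x$traits, " ", round(100 * ds$A_share_ri), "%", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.riclpm_fit <- function(object, ...) {
  out <- list(fit = object, stability = derived_stability(object))
  class(out) <- "summary.riclpm_fit"
  out
}

#' @export
print.summary.riclpm_fit <- function(x, ...) {
  print(x$fit)
  print(x$stability)
  invisible(x)
}

#' @export
logLik.riclpm_fit <- function(object, ...) {
  structure(-object$minus2lnL / 2, df = object$n_params,
            nobs = object$N, class = "logLik")
}

#' @export
coef.riclpm_fit <- function(object, ...) object$theta

#' @export
simulate.riclpm_fit <- function(object, nsim = 1, seed = 1, n_mz = NULL,
                                n_dz = NULL, ...) {
  if (is.null(n_mz)) n_mz <- object$n_mz
  if (is.null(n_dz)) n_dz <- object$n_dz
  out <- lapply(seq_len(nsim), function(i)
    simulate_riclpm_panel(object$params, n_mz, n_dz, seed = seed + i - 1L))
  if (nsim == 1L) out[[1L]] else out
}

## ---- fit indices -----------------------------------------------------------

#' Absolute fit indices for a fitted RI-CLPM
#'
#' Computes the model chi-square against the two-group saturated model
#' (unstructured mean vector and covariance per zygosity group), the baseline
#' (independence: free means and variances, zero covariances, per group)
#' chi-square, and CFI, TLI and RMSEA.  RMSEA uses the multi-group scaling
#' `sqrt(G * max(chi2 - df, 0) / (df * N))` with `G = 2` groups and `N` the
#' total number of pairs.  With complete data the saturated model is closed
#' form; with missing data it is estimated by EM.
#'
#' @param fit a `riclpm_fit`.
#' @param data optional [twin_panel()]; defaults to the data stored in `fit`.
#' @return list with `chi2_model`, `df_model`, `chi2_baseline`,
#'   `df_baseline`, `CFI`, `TLI`, `RMSEA`, `minus2lnL_saturated`.
#' @export
fit_indices <- function(fit, data = NULL) {
  Ys <- if (is.null(data)) fit$Y else
    list(MZ = riclpm_pair_matrix(data, fit$traits, "MZ"),
         DZ = riclpm_pair_matrix(data, fit$traits, "DZ"))
  sat <- sum(vapply(Ys, function(Y) mvn_saturated(Y)$neg2ll, 0))
  base <- sum(vapply(Ys, mvn_independence, 0))
  p <- 12L
  n_moments <- 2L * (p + p * (p + 1L) / 2L)
  chi2_m <- max(fit$minus2lnL - sat, 0)
  df_m <- n_moments - fit$n_params
  chi2_b <- max(base - sat, 0)
  df_b <- n_moments - 2L * (2L * p)
  num_m <- max(chi2_m - df_m, 0)
  num_b <- max(chi2_b - df_b, num_m)
  CFI <- if (num_b > 0) 1 - num_m / num_b else 1
  rat_b <- chi2_b / df_b
  rat_m <- chi2_m / df_m
  TLI <- if (rat_b > 1) (rat_b - rat_m) / (rat_b - 1) else 1
  TLI <- min(TLI, 1)
  N <- fit$N
  RMSEA <- sqrt(2 * max(chi2_m - df_m, 0) / (df_m * N))
  list(chi2_model = chi2_m, df_model = df_m, chi2_baseline = chi2_b,
       df_baseline = df_b, CFI = CFI, TLI = TLI, RMSEA = RMSEA,
       minus2lnL_saturated = sat)
}

## ---- cross-lag tests -------------------------------------------------------

riclpm_crosslag_index <- function(traits) {
  ## theta positions of the four cross-lagged paths
  data.frame(
    index = c(8L, 9L, 12L, 13L),
    label = c(paste0(traits[2], "_w1 -> ", traits[1], "_w2"),
              paste0(traits[1], "_w1 -> ", traits[2], "_w2"),
              paste0(traits[2], "_w2 -> ", traits[1], "_w3"),
              paste0(traits[1], "_w2 -> ", traits[2], "_w3")),
    stringsAsFactors = FALSE)
}

#' Likelihood-ratio tests of the cross-lagged paths
#'
#' Refits the model with each of the four cross-lagged paths fixed to zero in
#' turn (warm-started from the full fit) and reports the likelihood-ratio
#' chi-square (1 df) and p-value.  A non-significant difference means the
#' restricted model fits no worse than the full model.
#'
#' @param data the [twin_panel()] the full model was fitted to.
#' @param full_fit a converged `riclpm_fit`.
#' @return data frame with one row per path: `path`, `estimate`
#'   (unstandardized), `chi2_diff`, `df`, `p_value`.
#' @export
test_cross_lags <- function(data, full_fit) {
  idx <- riclpm_crosslag_index(full_fit$traits)
  out <- idx
  out$estimate <- full_fit$theta[idx$index]
  out$chi2_diff <- NA_real_
  out$df <- 1L
  out$p_value <- NA_real_
  for (i in seq_len(nrow(idx))) {
    j <- idx$index[i]
    fx <- c(full_fit$fixed, stats::setNames(0, j))
    res <- tryCatch(
      fit_riclpm(data, full_fit$traits, fixed = fx,
                 start = full_fit$theta, n_starts = 1L),
      error = function(e) NULL)
    if (is.null(res)) next
    out$chi2_diff[i] <- max(res$minus2lnL - full_fit$minus2lnL, 0)
    out$p_value[i] <- stats::pchisq(out$chi2_diff[i], 1L, lower.tail = FALSE)
  }
  out[, c("label", "estimate", "chi2_diff", "df", "p_value")]
}

## ---- derived stability -----------------------------------------------------

#' Derived stability quantities of a fitted (or specified) RI-CLPM
#'
#' For each trait: the proportion of total variance explained by the random
#' intercept at each wave (`ri_share`), the A and E shares of random-intercept
#' variance, the genetic and environmental correlations between the two
#' random intercepts, and standardized autoregressive/cross-lagged paths
#' (`path * SD(w_source, t) / SD(w_target, t + 1)`, SDs of the total
#' within-person components).
#'
#' @param fit a `riclpm_fit` or a [riclpm_params()] object.
#' @return an object of class `riclpm_stability` (a list).
#' @export
derived_stability <- function(fit) {
  params <- if (inherits(fit, "riclpm_fit")) fit$params else fit
  stopifnot(inherits(params, "riclpm_params"))
  V_ri <- params$VA_ri + params$VE_ri
  V1 <- params$SA_w1 + params$SE_w1
  U2 <- params$SA_u2 + params$SE_u2
  U3 <- params$SA_u3 + params$SE_u3
  V2 <- params$B1 %*% V1 %*% t(params$B1) + U2
  V3 <- params$B2 %*% V2 %*% t(params$B2) + U3
  Vw <- list(V1, V2, V3)
  ri_share <- sapply(1:3, function(t) diag(V_ri) / (diag(V_ri) + diag(Vw[[t]])))
  dimnames(ri_share) <- list(params$traits, paste0("wave", 1:3))
  A_share <- diag(params$VA_ri) / pmax(diag(V_ri), 1e-12)
  names(A_share) <- params$traits
  rA <- params$VA_ri[1, 2] / sqrt(prod(pmax(diag(params$VA_ri), 1e-12)))
  rE <- params$VE_ri[1, 2] / sqrt(prod(pmax(diag(params$VE_ri), 1e-12)))
  stdize <- function(B, Vfrom, Vto) {
    out <- B
    for (i in 1:2) for (j in 1:2)
      out[i, j] <- B[i, j] * sqrt(Vfrom[j, j] / Vto[i, i])
    dimnames(out) <- list(paste0("to_", params$traits),
                          paste0("from_", params$traits))
    out
  }
  structure(list(
    ri_share = ri_share, A_share_ri = A_share, E_share_ri = 1 - A_share,
    rA_ri = rA, rE_ri = rE,
    std_paths = list(w1_to_w2 = stdize(params$B1, V1, V2),
                     w2_to_w3 = stdize(params$B2, V2, V3)),
    within_var = Vw, ri_var = V_ri), class = "riclpm_stability")
}

#' @export
print.riclpm_stability <- function(x, ...) {
  cat("Time-invariant stability (random intercepts)\n")
  cat("  Share of total variance explained by the RI:\n")
  print(round(100 * x$ri_share))
  cat("  A / E share of RI variance:\n")
  print(round(100 * rbind(A = x$A_share_ri, E = x$E_share_ri)))
  cat("  RI correlations: rA = ", round(x$rA_ri, 3), ", rE = ",
      round(x$rE_ri, 3), "\n", sep = "")
  cat("  Standardized paths w1 -> w2:\n")
  print(round(x$std_paths$w1_to_w2, 3))
  cat("  Standardized paths w2 -> w3:\n")
  print(round(x$std_paths$w2_to_w3, 3))
  invisible(x)
}
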