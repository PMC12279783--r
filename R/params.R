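## Parameter containers for the generators and models.

sym2 <- function(v1, v2, cov, labels = NULL) {
  m <- matrix(c(v1, cov, cov, v2), 2L, 2L)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

check_psd <- function(m, name, tol = 1e-10) {
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop(name, " must be symmetric")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1))
    stop(name, " must be positive semidefinite (min eigenvalue ",
         format(min(ev)), ")")
  invisible(m)
}

#' Parameters of the biometric random-intercept cross-lagged panel model
#'
#' The model decomposes each of two traits, observed at three waves, into a
#' time-invariant random intercept (RI) and a within-person process `w`.
#' Both parts are split into additive-genetic (A) and non-shared environmental
#' (E) components; A components correlate 1 across MZ co-twins and 0.5 across
#' DZ co-twins, E components are twin-specific.  The within-person process
#' follows first-order dynamics `w[t+1] = B[t] %*% w[t] + u[t+1]` with
#' interval-specific 2x2 path matrices `B[t]` (diagonal: autoregression;
#' off-diagonal: cross-lagged paths) shared by the A and E streams, and
#' innovations `u` with their own A/E covariances.
#'
#' All 2x2 covariance blocks are over the two traits in the order given by
#' `traits`.
#'
#' @param VA_ri,VE_ri 2x2 A- and E-covariance matrices of the random
#'   intercepts.
#' @param B1,B2 2x2 within-person path matrices for wave 1 to 2 and 2 to 3;
#'   entry `[i, j]` is the path from trait `j` at wave t to trait `i` at
#'   wave t+1.
#' @param SA_w1,SE_w1 2x2 A/E covariances of the wave-1 within-person
#'   component.
#' @param SA_u2,SE_u2,SA_u3,SE_u3 2x2 A/E innovation covariances at waves 2
#'   and 3.
#' @param mu 2x3 matrix of means (trait by wave).
#' @param sex_effect length-2 mean shift added for sex = 1 (female), per trait.
#' @param traits trait labels, default `c("personality", "psychopathology")`.
#' @return an object of class `riclpm_params`.
#' @seealso [simulate_riclpm_panel()], [riclpm_implied_moments()],
#'   [fit_riclpm()]
#' @export
riclpm_params <- function(VA_ri, VE_ri, B1, B2, SA_w1, SE_w1,
                          SA_u2, SE_u2, SA_u3, SE_u3,
                          mu = matrix(0, 2L, 3L), sex_effect = c(0, 0),
                          traits = c("personality", "psychopathology")) {
  blocks <- list(VA_ri = VA_ri, VE_ri = VE_ri, SA_w1 = SA_w1, SE_w1 = SE_w1,
                 SA_u2 = SA_u2, SE_u2 = SE_u2, SA_u3 = SA_u3, SE_u3 = SE_u3)
  for (nm in names(blocks)) {
    if (!is.matrix(blocks[[nm]]) || any(dim(blocks[[nm]]) != 2L))
      stop(nm, " must be a 2x2 matrix")
    check_psd(blocks[[nm]], nm)
  }
  stopifnot(is.matrix(B1), all(dim(B1) == 2L),
            is.matrix(B2), all(dim(B2) == 2L),
            is.matrix(mu), all(dim(mu) == c(2L, 3L)),
            length(sex_effect) == 2L, length(traits) == 2L)
  structure(c(blocks, list(B1 = B1, B2 = B2, mu = mu,
                           sex_effect = sex_effect,
                           traits = as.character(traits))),
            class = "riclpm_params")
}

#' @export
print.riclpm_params <- function(x, ...) {
  cat("Biometric RI-CLPM parameters (", paste(x$traits, collapse = ", "), ")\n",
      sep = "")
  cat("  RI variances  A:", signif(diag(x$VA_ri), 3),
      " E:", signif(diag(x$VE_ri), 3), "\n")
  rAri <- x$VA_ri[1, 2] / sqrt(prod(diag(x$VA_ri)))
  cat("  RI genetic correlation:", signif(rAri, 3), "\n")
  cat("  B1:\n"); print(signif(x$B1, 3))
  cat("  B2:\n"); print(signif(x$B2, 3))
  invisible(x)
}

#' Parameters of a multivariate Cholesky ACE/AE twin model
#'
#' A, C and E covariance matrices are parameterized through lower-triangular
#' path matrices (`A = a %*% t(a)` and so on), which keeps them positive
#' semidefinite by construction.  Means are per variable and per sex.
#'
#' @param a,e m x m lower-triangular path matrices for additive-genetic and
#'   non-shared environmental influences.
#' @param c optional m x m lower-triangular shared-environment path matrix;
#'   `NULL` gives an AE model.
#' @param means m x 2 matrix of means, columns male / female.
#' @param variables character vector of m variable labels of the form
#'   `<trait>_<wave>`.
#' @return an object of class `cholesky_params`.
#' @seealso [simulate_cholesky_panel()], [implied_pair_moments()],
#'   [fit_cholesky()]
#' @export
cholesky_params <- function(a, e, c = NULL, means = NULL, variables = NULL) {
  m <- nrow(a)
  if (is.null(c)) c <- matrix(0, m, m)
  if (is.null(means)) means <- matrix(0, m, 2L)
  if (is.null(variables)) variables <- paste0("v", seq_len(m), "_1")
  for (nm in c("a", "c", "e")) {
    mm <- get(nm)
    if (!is.matrix(mm) || any(dim(mm) != m))
      stop(nm, " must be ", m, "x", m)
    if (any(abs(mm[upper.tri(mm)]) > 0))
      stop(nm, " must be lower-triangular")
  }
  stopifnot(is.matrix(means), nrow(means) == m, ncol(means) == 2L,
            length(variables) == m)
  structure(list(a = a, c = c, e = e, means = means,
                 variables = as.character(variables)),
            class = "cholesky_params")
}

#' @export
print.cholesky_params <- function(x, ...) {
  cat("Cholesky twin-model parameters (", length(x$variables),
      " variables)\n", sep = "")
  A <- tcrossprod(x$a); C <- tcrossprod(x$c); E <- tcrossprod(x$e)
  tot <- diag(A) + diag(C) + diag(E)
  tab <- cbind(a2 = diag(A) / tot, c2 = diag(C) / tot, e2 = diag(E) / tot)
  rownames(tab) <- x$variables
  print(signif(tab, 3))
  invisible(x)
}

#' One-factor measurement parameters
#'
#' Loadings are constrained equal across waves; uniquenesses may vary by wave.
#'
#' @param loadings named numeric vector of factor loadings (one per
#'   indicator).
#' @param uniqueness numeric vector (recycled across waves) or k x n_waves
#'   matrix of unique variances; default `1 - loadings^2` at every wave.
#' @param n_waves number of waves (default 3).
#' @return an object of class `measurement_params`.
#' @export
measurement_params <- function(loadings, uniqueness = NULL, n_waves = 3L) {
  stopifnot(!is.null(names(loadings)), all(nzchar(names(loadings))))
  k <- length(loadings)
  if (is.null(uniqueness)) uniqueness <- 1 - loadings^2
  if (!is.matrix(uniqueness))
    uniqueness <- matrix(uniqueness, k, n_waves,
                         dimnames = list(names(loadings), NULL))
  if (any(uniqueness < 0)) stop("uniqueness must be nonnegative")
  structure(list(loadings = loadings, uniqueness = uniqueness,
                 n_waves = as.integer(n_waves)),
            class = "measurement_params")
}

#' Missingness specification
#'
#' Wave-level dropout (a twin's entire wave missing) plus cell-level
#' missing-completely-at-random, both independent across twins.
#'
#' @param wave_dropout numeric vector of per-wave dropout probabilities.
#' @param cell_mcar per-cell MCAR probability.
#' @return an object of class `missingness_spec`.
#' @export
missingness_spec <- function(wave_dropout = c(0, 0, 0), cell_mcar = 0) {
  stopifnot(all(wave_dropout >= 0), all(wave_dropout <= 1),
            cell_mcar >= 0, cell_mcar <= 1)
  structure(list(wave_dropout = wave_dropout, cell_mcar = cell_mcar),
            class = "missingness_spec")
}

#' Solve innovation covariances for target within-person moments
#'
#' Given the wave-1 within-person covariance, the path matrices and target
#' within-person covariance matrices at waves 2 and 3, returns the innovation
#' covariances `U[t] = V[t] - B[t-1] V[t-1] t(B[t-1])`.  Errors if a solved
#' innovation covariance is not positive semidefinite (targets unattainable
#' under the given dynamics).
#'
#' @param V1,V2,V3 target 2x2 within-person covariance matrices per wave.
#' @param B1,B2 2x2 path matrices.
#' @return list with elements `U2` and `U3`.
#' @export
solve_innovations <- function(V1, V2, V3, B1, B2) {
  U2 <- V2 - B1 %*% V1 %*% t(B1)
  U3 <- V3 - B2 %*% V2 %*% t(B2)
  check_psd(U2, "U2 (wave-2 innovation covariance)")
  check_psd(U3, "U3 (wave-3 innovation covariance)")
  list(U2 = U2, U3 = U3)
}

#' Study-calibrated RI-CLPM generating parameters
#'
#' Default generating values for the biometric RI-CLPM simulator, calibrated
#' so that the implied structure reproduces the reference estimates the
#' package's recovery suite targets: random-intercept variance shares of
#' 53/58/64% (personality) and 39/38/45% (psychopathology) across the three
#' waves, A-shares of RI variance 70% (personality) and 83% (psychopathology),
#' an RI genetic correlation of -0.55, and (optionally) a single non-zero
#' cross-lagged path, personality wave 2 to psychopathology wave 3, with
#' standardized value `crosslag_std` (default 0.10).  Quantities the reference
#' estimates do not pin down are package choices, documented in the methods
#' vignette: within-process cross-trait correlation -0.30, RI E-correlation
#' -0.30, within-process A-share 0.35, autoregressive paths 0.35/0.40, and
#' sex mean effects (+0.2, -0.3).  Wave-3 total variance is scaled to 1 per
#' trait.
#'
#' @param crosslag_std standardized personality-W2 to psychopathology-W3
#'   cross-lagged path (set 0 for a no-cross-lag generator).
#' @param sex_effect length-2 sex mean shift (personality, psychopathology).
#' @return an object of class [riclpm_params()].
#' @export
default_riclpm_params <- function(crosslag_std = 0.10,
                                  sex_effect = c(0.2, -0.3)) {
  ri_share <- rbind(personality = c(0.53, 0.58, 0.64),
                    psychopathology = c(0.39, 0.38, 0.45))
  a_share_ri <- c(personality = 0.70, psychopathology = 0.83)
  rA_ri <- -0.55
  rE_ri <- -0.30
  within_cor <- -0.30
  within_a_share <- 0.35
  autoreg <- c(personality = 0.35, psychopathology = 0.40)

  ## wave-3 total variance fixed at 1: V_ri = share_3, Vw3 = 1 - share_3
  v_ri <- ri_share[, 3]
  vw <- sapply(1:3, function(t) v_ri * (1 - ri_share[, t]) / ri_share[, t])
  Vt <- lapply(1:3, function(t) {
    cv <- within_cor * sqrt(vw[1, t] * vw[2, t])
    sym2(vw[1, t], vw[2, t], cv)
  })
  B1 <- diag(autoreg)
  B2 <- diag(autoreg)
  ## cross-lag: personality (trait 1) W2 -> psychopathology (trait 2) W3
  B2[2, 1] <- crosslag_std * sqrt(Vt[[3]][2, 2] / Vt[[2]][1, 1])
  U <- solve_innovations(Vt[[1]], Vt[[2]], Vt[[3]], B1, B2)

  VA_ri_d <- a_share_ri * v_ri
  VE_ri_d <- (1 - a_share_ri) * v_ri
  VA_ri <- sym2(VA_ri_d[1], VA_ri_d[2], rA_ri * sqrt(prod(VA_ri_d)))
  VE_ri <- sym2(VE_ri_d[1], VE_ri_d[2], rE_ri * sqrt(prod(VE_ri_d)))

  riclpm_params(
    VA_ri = VA_ri, VE_ri = VE_ri, B1 = B1, B2 = B2,
    SA_w1 = within_a_share * Vt[[1]], SE_w1 = (1 - within_a_share) * Vt[[1]],
    SA_u2 = within_a_share * U$U2,   SE_u2 = (1 - within_a_share) * U$U2,
    SA_u3 = within_a_share * U$U3,   SE_u3 = (1 - within_a_share) * U$U3,
    mu = matrix(0, 2, 3), sex_effect = sex_effect)
}

#' Study-calibrated bivariate AE Cholesky generating parameters
#'
#' Bivariate AE model for the aggregated (cross-wave composite)
#' psychopathology and personality factors: standardized genetic variances
#' 0.63 and 0.57, genetic correlation -0.513, environmental correlation
#' -0.374, unit total variances, sex mean effects as in
#' [default_riclpm_params()].
#'
#' @return an object of class [cholesky_params()].
#' @export
default_composite_cholesky_params <- function() {
  a2 <- c(psychopathology = 0.63, personality = 0.57)
  e2 <- 1 - a2
  rA <- -0.513
  rE <- -0.374
  A <- sym2(a2[1], a2[2], rA * sqrt(prod(a2)))
  E <- sym2(e2[1], e2[2], rE * sqrt(prod(e2)))
  cholesky_params(a = t(chol(A)), e = t(chol(E)),
                  means = cbind(male = c(0, 0), female = c(-0.3, 0.2)),
                  variables = c("psychopathology_1", "personality_1"))
}

#' Reference one-factor loadings for the two general factors
#'
#' Standardized loadings used by the measurement-recovery suite: Big Five
#' traits on the general personality factor (-0.55, 0.71, 0.65, 0.25, 0.53)
#' and seven symptom scales on the general psychopathology factor (0.80,
#' 0.67, 0.73, 0.58, 0.41, 0.41, 0.40), with uniqueness `1 - loading^2`.
#'
#' @return named list of [measurement_params()] for `personality` and
#'   `psychopathology`.
#' @export
default_measurement_params <- function() {
  list(
    personality = measurement_params(c(
      neuroticism = -0.55, extraversion = 0.71, openness = 0.65,
      agreeableness = 0.25, conscientiousness = 0.53)),
    psychopathology = measurement_params(c(
      depressive = 0.80, anxiety = 0.67, somatic = 0.73, eating = 0.58,
      delinquency = 0.41, conduct = 0.41, substance = 0.40))
  )
}

#' Default missingness emulating wave attrition
#'
#' Wave participation fractions of roughly 1.00 / 0.76 / 0.63 (dropout
#' probabilities 0, 0.24, 0.37) plus 1% cell-level MCAR.
#' @return a [missingness_spec()].
#' @export
default_missingness_spec <- function() {
  missingness_spec(wave_dropout = c(0, 0.24, 0.37), cell_mcar = 0.01)
}
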