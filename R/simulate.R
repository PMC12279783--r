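## Twin-panel simulators.  All draws are structural (component streams are
## drawn and combined), never from the implied joint covariance, so the
## implied-moment builders remain an independent oracle.

## draw n pair-level realizations of a 2x2-covariance component with
## cross-twin correlation r; returns list(t1 = n x 2, t2 = n x 2)
draw_pair_component <- function(n, S, r) {
  if (n == 0L) return(list(t1 = matrix(0, 0, 2), t2 = matrix(0, 0, 2)))
  if (all(S == 0)) return(list(t1 = matrix(0, n, 2), t2 = matrix(0, n, 2)))
  S4 <- rbind(cbind(S, r * S), cbind(r * S, S))
  x <- MASS::mvrnorm(n, rep(0, 4L), S4)
  if (is.null(dim(x))) x <- matrix(x, 1L)
  list(t1 = x[, 1:2, drop = FALSE], t2 = x[, 3:4, drop = FALSE])
}

#' Simulate twin pairs under the biometric RI-CLPM
#'
#' Draws random intercepts and within-person processes for both traits, with
#' additive-genetic components correlated 1 (MZ) or 0.5 (DZ) across co-twins
#' and non-shared environmental components independent, propagates the
#' within-person dynamics `w[t+1] = B[t] w[t] + u[t+1]`, and returns observed
#' scores `mu + sex_effect * sex + RI + w[t]`.  MZ co-twins share one sex;
#' DZ co-twins' sexes are independent Bernoulli(0.5).
#'
#' @param params a [riclpm_params()] object.
#' @param n_mz,n_dz numbers of MZ and DZ pairs (defaults mirror the reference
#'   sample composition, 577:961).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return a [twin_panel()] with the two traits at three waves.
#' @export
simulate_riclpm_panel <- function(params, n_mz = 577L, n_dz = 961L, seed) {
  stopifnot(inherits(params, "riclpm_params"), n_mz >= 0L, n_dz >= 0L)
  set.seed(seed)
  sim_group <- function(n, r, zyg) {
    ri_a <- draw_pair_component(n, params$VA_ri, r)
    w_a <- vector("list", 3L)
    w_a[[1L]] <- draw_pair_component(n, params$SA_w1, r)
    u_a2 <- draw_pair_component(n, params$SA_u2, r)
    u_a3 <- draw_pair_component(n, params$SA_u3, r)
    ri_e <- draw_pair_component(n, params$VE_ri, 0)
    w_e <- vector("list", 3L)
    w_e[[1L]] <- draw_pair_component(n, params$SE_w1, 0)
    u_e2 <- draw_pair_component(n, params$SE_u2, 0)
    u_e3 <- draw_pair_component(n, params$SE_u3, 0)
    for (tw in c("t1", "t2")) {
      w_a[[2L]][[tw]] <- w_a[[1L]][[tw]] %*% t(params$B1) + u_a2[[tw]]
      w_a[[3L]][[tw]] <- w_a[[2L]][[tw]] %*% t(params$B2) + u_a3[[tw]]
      w_e[[2L]][[tw]] <- w_e[[1L]][[tw]] %*% t(params$B1) + u_e2[[tw]]
      w_e[[3L]][[tw]] <- w_e[[2L]][[tw]] %*% t(params$B2) + u_e3[[tw]]
    }
    if (zyg == "MZ") {
      sex1 <- stats::rbinom(n, 1L, 0.5); sex2 <- sex1
    } else {
      sex1 <- stats::rbinom(n, 1L, 0.5); sex2 <- stats::rbinom(n, 1L, 0.5)
    }
    df <- data.frame(pair_id = paste0(tolower(zyg), seq_len(n), recycle0 = TRUE),
                     zygosity = rep(zyg, n), sex_t1 = sex1, sex_t2 = sex2,
                     stringsAsFactors = FALSE)
    for (tw in 1:2) {
      twl <- c("t1", "t2")[tw]
      sex <- if (tw == 1L) sex1 else sex2
      for (w in 1:3) for (k in 1:2) {
        y <- params$mu[k, w] + params$sex_effect[k] * sex +
          ri_a[[twl]][, k] + ri_e[[twl]][, k] +
          w_a[[w]][[twl]][, k] + w_e[[w]][[twl]][, k]
        df[[paste0(params$traits[k], "_", w, "_", twl)]] <- y
      }
    }
    df
  }
  out <- rbind(sim_group(n_mz, 1, "MZ"), sim_group(n_dz, 0.5, "DZ"))
  twin_panel(out, traits = params$traits, waves = 1:3)
}

#' Simulate twin pairs under a Cholesky ACE model
#'
#' Per-pair draws with within-twin covariance `A + C + E` and cross-twin
#' covariance `A + C` (MZ) or `0.5 A + C` (DZ), where `A = a a'`, `C = c c'`,
#' `E = e e'`; sex-specific means are added (MZ co-twins share one sex, DZ
#' sexes are independent).
#'
#' @param params a [cholesky_params()] object.
#' @param n_mz,n_dz numbers of MZ and DZ pairs.
#' @param seed integer seed.
#' @return a [twin_panel()] over the variables named in `params$variables`.
#' @export
simulate_cholesky_panel <- function(params, n_mz = 577L, n_dz = 961L, seed) {
  stopifnot(inherits(params, "cholesky_params"), n_mz >= 0L, n_dz >= 0L)
  set.seed(seed)
  m <- nrow(params$a)
  vr <- parse_variables(params$variables)
  sim_group <- function(n, r, zyg) {
    if (n > 0L) {
      SA <- rbind(cbind(diag(m), r * diag(m)), cbind(r * diag(m), diag(m)))
      Af <- MASS::mvrnorm(n, rep(0, 2L * m), SA)
      if (is.null(dim(Af))) Af <- matrix(Af, 1L)
      Cf <- matrix(stats::rnorm(n * m), n, m)   # shared: same factor both twins
      E1 <- matrix(stats::rnorm(n * m), n, m)
      E2 <- matrix(stats::rnorm(n * m), n, m)
      y1 <- Af[, 1:m, drop = FALSE] %*% t(params$a) + Cf %*% t(params$c) +
        E1 %*% t(params$e)
      y2 <- Af[, m + 1:m, drop = FALSE] %*% t(params$a) + Cf %*% t(params$c) +
        E2 %*% t(params$e)
    } else {
      y1 <- y2 <- matrix(0, 0L, m)
    }
    if (zyg == "MZ") {
      sex1 <- stats::rbinom(n, 1L, 0.5); sex2 <- sex1
    } else {
      sex1 <- stats::rbinom(n, 1L, 0.5); sex2 <- stats::rbinom(n, 1L, 0.5)
    }
    y1 <- y1 + t(params$means[, sex1 + 1L, drop = FALSE])
    y2 <- y2 + t(params$means[, sex2 + 1L, drop = FALSE])
    df <- data.frame(pair_id = paste0(tolower(zyg), seq_len(n), recycle0 = TRUE),
                     zygosity = rep(zyg, n), sex_t1 = sex1, sex_t2 = sex2,
                     stringsAsFactors = FALSE)
    for (j in seq_len(m)) {
      df[[paste0(params$variables[j], "_t1")]] <- y1[, j]
      df[[paste0(params$variables[j], "_t2")]] <- y2[, j]
    }
    df
  }
  out <- rbind(sim_group(n_mz, 1, "MZ"), sim_group(n_dz, 0.5, "DZ"))
  ## order columns into canonical layout
  twin_panel(out, traits = vr$traits, waves = vr$waves)
}

## split "<trait>_<wave>" labels into trait/wave grids, checking completeness
parse_variables <- function(variables) {
  m <- regmatches(variables, regexec("^(.*)_([0-9]+)$", variables))
  if (any(lengths(m) != 3L))
    stop("variables must be of the form <trait>_<wave>")
  tr <- vapply(m, `[`, "", 2L)
  wv <- as.integer(vapply(m, `[`, "", 3L))
  traits <- unique(tr); waves <- sort(unique(wv))
  if (!setequal(variables, tp_vars(traits, waves)))
    stop("variables must form a complete trait x wave grid")
  list(traits = traits, waves = waves)
}

#' Generate observed indicators from latent general-factor scores
#'
#' Each indicator is `loading * factor + unique error`, with loadings equal
#' across waves and unique variances per wave, i.e. the one-factor
#' measurement structure the general-factor models assume.
#'
#' @param factor_panel a [twin_panel()] whose traits are true factor scores.
#' @param mp a named list of [measurement_params()], one per factor trait;
#'   indicator labels come from `names(mp[[trait]]$loadings)`.
#' @param seed integer seed.
#' @return a [twin_panel()] over all indicators.
#' @export
emit_indicators <- function(factor_panel, mp, seed) {
  stopifnot(all(names(mp) %in% tp_traits(factor_panel)))
  set.seed(seed)
  waves <- tp_waves(factor_panel)
  out <- factor_panel[, c("pair_id", "zygosity", "sex_t1", "sex_t2")]
  n <- nrow(out)
  indicators <- character()
  for (trait in names(mp)) {
    lam <- mp[[trait]]$loadings
    psi <- mp[[trait]]$uniqueness
    indicators <- c(indicators, names(lam))
    for (tw in c("t1", "t2")) for (w in seq_along(waves)) {
      f <- factor_panel[[paste0(trait, "_", waves[w], "_", tw)]]
      for (j in seq_along(lam)) {
        y <- lam[j] * f + stats::rnorm(n, 0, sqrt(psi[j, w]))
        out[[paste0(names(lam)[j], "_", waves[w], "_", tw)]] <- y
      }
    }
  }
  twin_panel(out, traits = indicators, waves = waves)
}

#' Mask cells of a twin panel at random
#'
#' Applies per-twin wave-level dropout (all of a twin's scores at a wave set
#' missing) and cell-level MCAR masking, independently across twins.
#'
#' @param data a [twin_panel()].
#' @param spec a [missingness_spec()].
#' @param seed integer seed.
#' @return the masked panel.
#' @export
apply_missingness <- function(data, spec, seed) {
  stopifnot(inherits(spec, "missingness_spec"))
  set.seed(seed)
  traits <- tp_traits(data); waves <- tp_waves(data)
  n <- nrow(data)
  for (tw in c("t1", "t2")) {
    for (w in seq_along(waves)) {
      p <- if (w <= length(spec$wave_dropout)) spec$wave_dropout[w] else 0
      drop <- stats::runif(n) < p
      for (trait in traits) {
        cn <- paste0(trait, "_", waves[w], "_", tw)
        mask <- drop | (stats::runif(n) < spec$cell_mcar)
        data[[cn]][mask] <- NA_real_
      }
    }
  }
  data
}
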