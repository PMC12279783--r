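make_indicator_panel <- function(n_pairs, seed, wave_cor = 0.6,
                                 mp = default_measurement_params()["psychopathology"]) {
  Phi <- matrix(wave_cor, 3, 3); diag(Phi) <- 1
  fp <- cholesky_params(a = matrix(0, 3, 3), e = t(chol(Phi)),
                        variables = paste0("psychopathology_", 1:3))
  fpan <- simulate_cholesky_panel(fp, 0, n_pairs, seed = seed)
  list(factors = fpan,
       indicators = emit_indicators(fpan, mp, seed = seed + 1))
}

test_that("FCS imputation is the identity on complete data and preserves the correlation structure", {
  d <- simulate_riclpm_panel(default_riclpm_params(), 100, 150, seed = 21)
  expect_identical(impute_fcs(d, 2, 2, seed = 1), d)

  ## 20% MCAR at 3000 pairs.  A single stochastic chain preserves the
  ## correlation structure within 0.03; the cell-wise mean over chains
  ## (the estimator actually used downstream) replaces draws by approximate
  ## conditional means, which mildly inflates the strongest correlations, so
  ## its bound is wider (0.06, established by this simulation oracle).
  dc <- simulate_riclpm_panel(default_riclpm_params(), 1200, 1800, seed = 22)
  dm <- apply_missingness(dc, missingness_spec(cell_mcar = 0.2), seed = 23)
  C_true <- cor(individual_matrix(dc))
  d1 <- impute_fcs(dm, 1, 10, seed = 24)
  expect_lt(max(abs(cor(individual_matrix(d1)) - C_true)), 0.03)
  di <- impute_fcs(dm, 10, 10, seed = 24)
  expect_lt(max(abs(cor(individual_matrix(di)) - C_true)), 0.06)
  expect_false(anyNA(individual_matrix(di)))

  ## a variable with no observed values is an error naming it
  d_bad <- dc
  d_bad$personality_2_t1 <- NA_real_
  d_bad$personality_2_t2 <- NA_real_
  expect_error(impute_fcs(d_bad, 2, 2, seed = 1), "personality_2")
})

test_that("near-deterministic relationships are reproduced by imputation", {
  ## two almost perfectly collinear variables: the imputed value must track
  ## the deterministic linear prediction
  set.seed(31)
  n <- 400
  x <- rnorm(2 * n)
  y <- 2 * x + rnorm(2 * n, 0, 0.01)
  df <- data.frame(pair_id = paste0("p", 1:n), zygosity = rep(c("MZ", "DZ"),
                                                              length.out = n),
                   sex_t1 = 0L, sex_t2 = 1L,
                   a_1_t1 = x[1:n], a_1_t2 = x[n + 1:n],
                   b_1_t1 = y[1:n], b_1_t2 = y[n + 1:n])
  d <- twin_panel(df, traits = c("a", "b"), waves = 1L)
  truth <- d$b_1_t1[1]
  d$b_1_t1[1] <- NA
  di <- impute_fcs(d, 20, 5, seed = 32)
  expect_lt(abs(di$b_1_t1[1] - truth), 0.05)
})

test_that("constrained one-factor model recovers generating loadings", {
  sim <- make_indicator_panel(10000, seed = 41)
  gf <- fit_general_factor(sim$indicators,
                           default_trait_specs()$psychopathology)
  truth <- default_measurement_params()$psychopathology$loadings
  expect_equal(unname(gf$lambda), unname(truth), tolerance = 0.025)
  ## anchor orientation: depressive symptoms loads positively
  expect_gt(gf$lambda["depressive"], 0)
  ## inter-wave factor correlations near the generating 0.6
  expect_equal(gf$Phi[lower.tri(gf$Phi)], rep(0.6, 3), tolerance = 0.04)
  ## explained variance equals the parameter-level identity
  expect_equal(gf$explained_variance,
               mean(gf$lambda^2 / (gf$lambda^2 + gf$psi)), tolerance = 1e-12)

  ## null-loading generator: the identified quantity is the implied common
  ## covariance structure Lambda Phi Lambda', which must vanish (individual
  ## loadings are not separately identified from Phi when the factors carry
  ## no covariance: one loading can grow while Phi -> 0 on a flat ridge)
  mp0 <- list(psychopathology = measurement_params(
    setNames(rep(0, 7), names(truth)), uniqueness = 1))
  sim0 <- make_indicator_panel(10000, seed = 42, mp = mp0)
  gf0 <- fit_general_factor(sim0$indicators,
                            default_trait_specs()$psychopathology)
  k <- 7
  L0 <- matrix(0, 21, 3)
  for (w in 1:3) L0[(w - 1) * k + 1:k, w] <- gf0$lambda
  common <- L0 %*% gf0$Phi %*% t(L0)
  expect_lt(max(abs(common[upper.tri(common)])), 0.05)
})

test_that("regression factor scores behave like Thurstone scores", {
  sim <- make_indicator_panel(4000, seed = 51)
  gf <- fit_general_factor(sim$indicators,
                           default_trait_specs()$psychopathology)
  sc <- factor_scores(gf, sim$indicators)
  m <- individual_matrix(sc)
  ## mean ~ 0 by construction over the estimation sample
  expect_lt(max(abs(colMeans(m))), 1e-8)
  ## score-truth correlation matches the closed-form determinacy
  k <- 7
  L <- matrix(0, 21, 3)
  for (w in 1:3) L[(w - 1) * k + 1:k, w] <- gf$lambda
  Sigma <- L %*% gf$Phi %*% t(L) + diag(as.vector(gf$psi), 21)
  CovFX <- gf$Phi %*% t(L)
  det_w1 <- sqrt((CovFX %*% solve(Sigma) %*% t(CovFX))[1, 1])
  r <- cor(m[, "psychopathology_1"],
           individual_matrix(sim$factors)[, "psychopathology_1"])
  expect_equal(r, det_w1, tolerance = 0.03)
  ## invariance to twin order and row shuffling
  sc_sw <- factor_scores(gf, swap_twins(sim$indicators))
  expect_equal(panel_matrix(sc_sw, 1), panel_matrix(sc, 2), tolerance = 1e-10)
  ## a twin/wave with all indicators missing gets a missing score
  broken <- sim$indicators
  for (ind in names(gf$lambda)) broken[[paste0(ind, "_2_t1")]][3] <- NA
  sc_b <- factor_scores(gf, broken)
  expect_true(is.na(sc_b$psychopathology_2_t1[3]))
  expect_false(is.na(sc_b$psychopathology_1_t1[3]))
})

test_that("near-zero uniqueness makes the score equivalent to the indicators", {
  Phi <- matrix(0.5, 3, 3); diag(Phi) <- 1
  fp <- cholesky_params(a = matrix(0, 3, 3), e = t(chol(Phi)),
                        variables = paste0("g_", 1:3))
  fpan <- simulate_cholesky_panel(fp, 0, 2000, seed = 52)
  mp <- list(g = measurement_params(c(i1 = 0.9, i2 = 0.9),
                                    uniqueness = 1e-4))
  ind <- emit_indicators(fpan, mp, seed = 53)
  gf <- suppressWarnings(
    fit_general_factor(ind, trait_spec("g", c("i1", "i2"), anchor = "i1")))
  sc <- factor_scores(gf, ind)
  r <- cor(individual_matrix(sc)[, "g_1"], individual_matrix(ind)[, "i1_1"])
  expect_gt(r, 0.999)
})

test_that("cross-wave composite aggregates shared variance", {
  ## perfectly correlated waves: the composite correlates 1 with each wave
  n <- 500
  set.seed(61)
  base <- rnorm(2 * n)
  df <- data.frame(pair_id = paste0("p", 1:n),
                   zygosity = rep(c("MZ", "DZ"), length.out = n),
                   sex_t1 = 0L, sex_t2 = 0L)
  for (w in 1:3) {
    df[[paste0("g_", w, "_t1")]] <- base[1:n]
    df[[paste0("g_", w, "_t2")]] <- base[n + 1:n]
  }
  d <- twin_panel(df, traits = "g", waves = 1:3)
  comp <- aggregate_composite(d)
  expect_equal(abs(cor(individual_matrix(comp)[, "g_1"], base)), 1,
               tolerance = 1e-6)

  ## independent waves: flagged as degenerate
  for (w in 1:3) {
    df[[paste0("g_", w, "_t1")]] <- rnorm(n)
    df[[paste0("g_", w, "_t2")]] <- rnorm(n)
  }
  d_ind <- twin_panel(df, traits = "g", waves = 1:3)
  expect_warning(aggregate_composite(d_ind), "degenerate")

  ## fewer than two observed waves: missing composite
  d_miss <- d
  d_miss$g_1_t1[5] <- d_miss$g_2_t1[5] <- NA
  comp_m <- aggregate_composite(d_miss)
  expect_true(is.na(comp_m$g_1_t1[5]))
})

test_that("composite of a stable trait is more twin-informative than single waves", {
  ## RI-dominated generator: occasion-specific noise attenuates single-wave
  ## MZ cross-twin correlations relative to the cross-wave composite
  p <- default_riclpm_params(crosslag_std = 0, sex_effect = c(0, 0))
  d <- simulate_riclpm_panel(p, 3000, 0, seed = 62)
  comp <- aggregate_composite(d, traits = "personality")
  r_comp <- cor(comp$personality_1_t1, comp$personality_1_t2)
  r_waves <- sapply(1:3, function(w)
    cor(d[[paste0("personality_", w, "_t1")]],
        d[[paste0("personality_", w, "_t2")]]))
  expect_gt(r_comp, max(r_waves))
})
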