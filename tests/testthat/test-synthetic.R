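test_that("degenerate RI-CLPM generators behave as specified", {
  z2 <- matrix(0, 2, 2)
  mu <- matrix(c(1, -1, 2, -2, 3, -3), 2, 3)
  p0 <- riclpm_params(VA_ri = z2, VE_ri = z2, B1 = z2, B2 = z2,
                      SA_w1 = z2, SE_w1 = z2, SA_u2 = z2, SE_u2 = z2,
                      SA_u3 = z2, SE_u3 = z2, mu = mu,
                      sex_effect = c(0.5, -0.5))
  d <- simulate_riclpm_panel(p0, 5, 5, seed = 1)
  for (w in 1:3) for (k in 1:2) {
    tr <- p0$traits[k]
    expect_equal(d[[paste0(tr, "_", w, "_t1")]],
                 mu[k, w] + c(0.5, -0.5)[k] * d$sex_t1, tolerance = 1e-12)
  }

  ## MZ pairs with all E variances zero: co-twins are identical series
  pA <- default_riclpm_params(sex_effect = c(0, 0))
  for (nm in c("VE_ri", "SE_w1", "SE_u2", "SE_u3")) pA[[nm]] <- z2
  pA <- do.call(riclpm_params, unclass(pA)[names(formals(riclpm_params))])
  dA <- simulate_riclpm_panel(pA, 50, 0, seed = 2)
  ## identical up to the numerical rank tolerance of the singular joint draw
  expect_lt(max(abs(panel_matrix(dA, 1) - panel_matrix(dA, 2))), 1e-6)

  ## non-PSD covariance block is rejected before sampling
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(riclpm_params(VA_ri = bad, VE_ri = z2, B1 = z2, B2 = z2,
                             SA_w1 = z2, SE_w1 = z2, SA_u2 = z2, SE_u2 = z2,
                             SA_u3 = z2, SE_u3 = z2),
               "positive semidefinite")
})

test_that("fixed seed reproduces simulations bit for bit", {
  p <- default_riclpm_params()
  d1 <- simulate_riclpm_panel(p, 30, 40, seed = 99)
  d2 <- simulate_riclpm_panel(p, 30, 40, seed = 99)
  expect_identical(d1, d2)
  cp <- default_composite_cholesky_params()
  expect_identical(simulate_cholesky_panel(cp, 20, 20, seed = 3),
                   simulate_cholesky_panel(cp, 20, 20, seed = 3))
})

test_that("Cholesky generator matches twin-correlation expectations", {
  ## E-only model: cross-twin covariance ~ 0 in both groups
  m <- diag(2)
  pe <- cholesky_params(a = 0 * m, e = m,
                        variables = c("x_1", "y_1"))
  d <- simulate_cholesky_panel(pe, 4000, 4000, seed = 4)
  for (z in c("MZ", "DZ")) {
    sub <- d[d$zygosity == z, ]
    cc <- cor(sub$x_1_t1, sub$x_1_t2)
    expect_lt(abs(cc), 3 / sqrt(sum(d$zygosity == z)))
  }
  ## pure additive univariate trait: DZ correlation ~ 0.5
  pa <- univ_ae_params(1 - 1e-12, "x_1")
  da <- simulate_cholesky_panel(pa, 0, 6000, seed = 5)
  r_dz <- cor(da$x_1_t1, da$x_1_t2)
  expect_equal(r_dz, 0.5, tolerance = 3 / sqrt(6000))
})

test_that("bivariate AE generator matches closed-form pair moments", {
  cp <- default_composite_cholesky_params()
  n <- 50000
  d <- simulate_cholesky_panel(cp, n, n, seed = 6)
  for (z in c("MZ", "DZ")) {
    mom <- implied_pair_moments(cp, z, c(0, 0))
    sub <- d[d$zygosity == z & d$sex_t1 == 0 & d$sex_t2 == 0, , drop = FALSE]
    sub <- twin_panel(sub, attr(d, "traits"), attr(d, "waves"))
    Y <- cbind(panel_matrix(sub, 1), panel_matrix(sub, 2))
    dev <- cov(Y) - mom$Sigma
    se <- cov_mc_se(mom$Sigma, nrow(Y))
    expect_lt(max(abs(dev) / se), sidak_z(sum(upper.tri(dev, diag = TRUE))))
  }
})

test_that("indicator emission reproduces the one-factor structure", {
  Phi <- matrix(0.6, 3, 3); diag(Phi) <- 1
  fp <- cholesky_params(a = matrix(0, 3, 3), e = t(chol(Phi)),
                        variables = paste0("g_", 1:3))
  fpan <- simulate_cholesky_panel(fp, 0, 5000, seed = 7)

  ## loading 1, uniqueness 0: indicator equals the factor exactly
  mp1 <- list(g = measurement_params(c(ind = 1), uniqueness = 0))
  ind1 <- emit_indicators(fpan, mp1, seed = 8)
  expect_equal(ind1$ind_1_t1, fpan$g_1_t1, tolerance = 1e-12)

  ## loading 0.8, uniqueness 0.36: indicator-factor correlation ~ 0.8
  mp2 <- list(g = measurement_params(c(dep = 0.8), uniqueness = 0.36))
  ind2 <- emit_indicators(fpan, mp2, seed = 9)
  r <- cor(individual_matrix(ind2)[, "dep_1"], individual_matrix(fpan)[, "g_1"])
  expect_equal(r, 0.8, tolerance = 3 * (1 - 0.8^2) / sqrt(10000))

  ## zero loadings: correlation indistinguishable from 0
  mp0 <- list(g = measurement_params(c(nil = 0), uniqueness = 1))
  ind0 <- emit_indicators(fpan, mp0, seed = 10)
  r0 <- cor(individual_matrix(ind0)[, "nil_1"], individual_matrix(fpan)[, "g_1"])
  expect_lt(abs(r0), 3 / sqrt(10000))
})

test_that("missingness masking matches its specification", {
  d <- simulate_riclpm_panel(default_riclpm_params(), 1000, 1500, seed = 11)
  expect_identical(apply_missingness(d, missingness_spec(c(0, 0, 0), 0), 1), d)
  all_gone <- apply_missingness(d, missingness_spec(cell_mcar = 1), seed = 2)
  expect_true(all(is.na(individual_matrix(all_gone))))
  spec <- missingness_spec(wave_dropout = c(0, 0.24, 0.37))
  dm <- apply_missingness(d, spec, seed = 3)
  m <- individual_matrix(dm)
  n_ind <- nrow(m)
  for (w in 1:3) {
    obs_frac <- mean(!is.na(m[, paste0("personality_", w)]))
    expe <- 1 - spec$wave_dropout[w]
    expect_equal(obs_frac, expe,
                 tolerance = 3 * sqrt(expe * (1 - expe) / n_ind) + 1e-12)
  }
})

test_that("simulator swaps of group labels leave marginal moments unchanged", {
  p <- default_riclpm_params(sex_effect = c(0, 0))
  d1 <- simulate_riclpm_panel(p, 20000, 5000, seed = 12)
  d2 <- simulate_riclpm_panel(p, 5000, 20000, seed = 13)
  v1 <- apply(individual_matrix(d1), 2, var)
  v2 <- apply(individual_matrix(d2), 2, var)
  expect_equal(v1, v2, tolerance = 0.05)
})
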