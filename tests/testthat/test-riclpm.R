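test_that("implied moments reduce correctly in degenerate cases", {
  z2 <- matrix(0, 2, 2)
  VA <- matrix(c(0.5, -0.2, -0.2, 0.4), 2, 2)
  VE <- matrix(c(0.3, 0.05, 0.05, 0.2), 2, 2)
  ## pure random-intercept twin model: B = 0, no within-person variance
  p_ri <- riclpm_params(VA_ri = VA, VE_ri = VE, B1 = z2, B2 = z2,
                        SA_w1 = z2, SE_w1 = z2, SA_u2 = z2, SE_u2 = z2,
                        SA_u3 = z2, SE_u3 = z2)
  mz <- riclpm_implied_moments(p_ri, "MZ")
  expect_equal(mz$Sigma[1:2, 7:8], VA, ignore_attr = TRUE)
  expect_equal(mz$Sigma[1:2, 1:2], VA + VE, ignore_attr = TRUE)
  ## every wave pair has the same block
  expect_equal(mz$Sigma[1:2, 5:6], VA + VE, ignore_attr = TRUE)

  ## all A parts zero: cross-twin blocks vanish in both groups
  p_e <- default_riclpm_params()
  for (nm in c("VA_ri", "SA_w1", "SA_u2", "SA_u3")) p_e[[nm]] <- z2
  p_e <- do.call(riclpm_params, unclass(p_e)[names(formals(riclpm_params))])
  for (z in c("MZ", "DZ")) {
    mom <- riclpm_implied_moments(p_e, z)
    expect_equal(max(abs(mom$Sigma[1:6, 7:12])), 0)
  }
})

test_that("R and compiled moment builders agree", {
  p <- default_riclpm_params()
  th <- twinsem:::riclpm_pack(p)
  cpp <- twinsem:::riclpm_moments_cpp(th)
  expect_equal(cpp$Sigma_mz, unname(riclpm_implied_moments(p, "MZ")$Sigma),
               tolerance = 1e-10)
  expect_equal(cpp$Sigma_dz, unname(riclpm_implied_moments(p, "DZ")$Sigma),
               tolerance = 1e-10)
  expect_equal(as.vector(cpp$mu), riclpm_implied_moments(p, "MZ")$mean,
               tolerance = 1e-12)
  ## pack/unpack round trip
  p2 <- twinsem:::riclpm_unpack(th)
  for (nm in c("VA_ri", "VE_ri", "B1", "B2", "SA_w1", "SE_u3", "mu"))
    expect_equal(p2[[nm]], p[[nm]], tolerance = 1e-10)
})

test_that("implied moments match large-sample simulator covariances", {
  p <- default_riclpm_params(sex_effect = c(0, 0))
  n <- 80000
  d <- simulate_riclpm_panel(p, n, n, seed = 91)
  for (z in c("MZ", "DZ")) {
    mom <- riclpm_implied_moments(p, z)
    Y <- pair_matrix_12(d, z)
    dev <- cov(Y) - mom$Sigma
    se <- cov_mc_se(mom$Sigma, n)
    expect_lt(max(abs(dev) / se), sidak_z(78))
  }
})

test_that("compiled FIML equals brute-force density summation", {
  p <- default_riclpm_params(sex_effect = c(0, 0))
  d <- simulate_riclpm_panel(p, 25, 35, seed = 92)
  th <- twinsem:::riclpm_pack(p)
  compute <- function(panel) {
    Ymz <- pair_matrix_12(panel, "MZ"); Ydz <- pair_matrix_12(panel, "DZ")
    cpp <- twinsem:::riclpm_neg2ll_cpp(th, twinsem:::fiml_pattern_stats(Ymz),
                                       twinsem:::fiml_pattern_stats(Ydz))
    brute <- mvn_neg2ll(Ymz, riclpm_implied_moments(p, "MZ")$mean,
                        riclpm_implied_moments(p, "MZ")$Sigma) +
      mvn_neg2ll(Ydz, riclpm_implied_moments(p, "DZ")$mean,
                 riclpm_implied_moments(p, "DZ")$Sigma)
    c(cpp = cpp, brute = brute)
  }
  v <- compute(d)
  expect_equal(v[["cpp"]], v[["brute"]], tolerance = 1e-10)
  ## with missing data the observed sub-vector densities are used
  dm <- apply_missingness(d, missingness_spec(c(0, 0.3, 0.4), 0.1), seed = 93)
  vm <- compute(dm)
  expect_equal(vm[["cpp"]], vm[["brute"]], tolerance = 1e-10)
  ## twin-order swap leaves the likelihood unchanged
  vs <- compute(swap_twins(dm))
  expect_equal(vs[["cpp"]], vm[["cpp"]], tolerance = 1e-10)
})

test_that("FIML fit recovers generating parameters at moderate n", {
  p <- default_riclpm_params()
  d <- residualize_on_sex(simulate_riclpm_panel(p, 1125, 1875, seed = 94))
  fit <- fit_riclpm(d)
  expect_true(fit$converged)
  st <- derived_stability(fit)
  truth <- derived_stability(p)
  expect_equal(st$rA_ri, truth$rA_ri, tolerance = 0.07)
  expect_equal(unname(st$A_share_ri), unname(truth$A_share_ri),
               tolerance = 0.08)
  expect_lt(max(abs(st$ri_share - truth$ri_share)), 0.06)
  expect_equal(fit$params$B2[2, 1], p$B2[2, 1], tolerance = 0.08)
  ## information criteria identities
  expect_equal(fit$AIC, fit$minus2lnL + 2 * 38)
  expect_equal(fit$BIC, fit$minus2lnL + 38 * log(fit$N))
})

test_that("cross-lag restrictions never improve the deviance and are detected", {
  p <- default_riclpm_params()     # one generating cross-lag (std 0.10)
  d <- residualize_on_sex(simulate_riclpm_panel(p, 1125, 1875, seed = 95))
  fit <- fit_riclpm(d)
  cl <- test_cross_lags(d, fit)
  expect_equal(nrow(cl), 4L)
  expect_true(all(cl$chi2_diff >= 0))
  ## the generating non-zero path (personality W2 -> psychopathology W3)
  ## produces the smallest p-value
  gen <- grep("^personality_w2", cl$label)
  expect_equal(which.min(cl$p_value), gen)
  expect_lt(cl$p_value[gen], 0.05)
})

test_that("fit indices take their boundary values at the saturated model", {
  p <- default_riclpm_params(sex_effect = c(0, 0))
  d <- simulate_riclpm_panel(p, 120, 180, seed = 96)
  Ys <- list(MZ = pair_matrix_12(d, "MZ"), DZ = pair_matrix_12(d, "DZ"))
  sat <- sum(vapply(Ys, function(Y) twinsem:::mvn_saturated(Y)$neg2ll, 0))
  pseudo <- structure(list(minus2lnL = sat, n_params = 38L,
                           N = 300L, Y = Ys, traits = p$traits),
                      class = "riclpm_fit")
  fi <- fit_indices(pseudo)
  expect_equal(fi$chi2_model, 0)
  expect_equal(fi$CFI, 1)
  expect_equal(fi$RMSEA, 0)
  ## a model as bad as the baseline earns CFI = 0
  pseudo_b <- pseudo
  pseudo_b$minus2lnL <- sum(vapply(Ys, twinsem:::mvn_independence, 0))
  pseudo_b$n_params <- 48L
  fi_b <- fit_indices(pseudo_b)
  expect_lt(fi_b$CFI, 0.05)
})

test_that("saturated EM agrees with the closed form and handles missingness", {
  p <- default_riclpm_params(sex_effect = c(0, 0))
  d <- simulate_riclpm_panel(p, 150, 0, seed = 97)
  Y <- pair_matrix_12(d, "MZ")
  closed <- twinsem:::mvn_saturated(Y)
  expect_equal(closed$neg2ll, mvn_neg2ll(Y, closed$mu, closed$Sigma),
               tolerance = 1e-8)
  Ym <- Y; Ym[sample(length(Ym), 0.15 * length(Ym))] <- NA
  em <- twinsem:::mvn_saturated(Ym)
  ## the EM solution beats moment plug-ins computed from available cases
  plug_mu <- colMeans(Ym, na.rm = TRUE)
  plug_S <- cov(Ym, use = "pairwise.complete.obs")
  plug_S <- twinsem:::make_pd(plug_S, 1e-4)
  expect_lt(em$neg2ll, mvn_neg2ll(Ym, plug_mu, plug_S))
  ## and is a fixed point: its own FIML evaluation matches
  expect_equal(em$neg2ll, mvn_neg2ll(Ym, em$mu, em$Sigma), tolerance = 1e-6)
})

test_that("derived stability identities hold exactly at known parameters", {
  p <- default_riclpm_params()
  st <- derived_stability(p)
  ## calibrated generator hits its target shares by construction
  expect_equal(unname(st$A_share_ri), c(0.70, 0.83), tolerance = 1e-12)
  expect_equal(st$rA_ri, -0.55, tolerance = 1e-12)
  expect_equal(unname(st$ri_share[1, ]), c(0.53, 0.58, 0.64),
               tolerance = 1e-10)
  expect_equal(unname(st$ri_share[2, ]), c(0.39, 0.38, 0.45),
               tolerance = 1e-10)
  expect_equal(st$std_paths$w2_to_w3[2, 1], 0.10, tolerance = 1e-10)
  ## B = 0, all-E within: closed-form share Var(RI)/(Var(RI)+Var(u))
  z2 <- matrix(0, 2, 2)
  VE <- diag(c(0.6, 0.8)); U <- diag(c(0.4, 0.2))
  p0 <- riclpm_params(VA_ri = z2, VE_ri = VE, B1 = z2, B2 = z2,
                      SA_w1 = z2, SE_w1 = U, SA_u2 = z2, SE_u2 = U,
                      SA_u3 = z2, SE_u3 = U)
  st0 <- derived_stability(p0)
  expect_equal(unname(st0$ri_share[, 2]),
               diag(VE) / (diag(VE) + diag(U)), tolerance = 1e-12)
  expect_equal(unname(st0$A_share_ri), c(0, 0))
})
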