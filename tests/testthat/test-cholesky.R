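biv_vars <- c("psychopathology_1", "personality_1")

test_that("implied pair moments follow the twin algebra", {
  cp <- default_composite_cholesky_params()
  A <- tcrossprod(cp$a); E <- tcrossprod(cp$e)
  mz <- implied_pair_moments(cp, "MZ", c("male", "female"))
  dz <- implied_pair_moments(cp, "DZ", c(0, 0))
  expect_equal(mz$Sigma[1:2, 3:4], A, ignore_attr = TRUE)
  expect_equal(dz$Sigma[1:2, 3:4], 0.5 * A, ignore_attr = TRUE)
  expect_equal(mz$Sigma[1:2, 1:2], A + E, ignore_attr = TRUE)
  expect_equal(mz$mean, c(cp$means[, 1], cp$means[, 2]), ignore_attr = TRUE)

  ## a = c = 0: block-diagonal pair covariance
  pe <- cholesky_params(a = matrix(0, 2, 2), e = cp$e, variables = biv_vars)
  me <- implied_pair_moments(pe, "MZ")
  expect_equal(me$Sigma[1:2, 3:4], matrix(0, 2, 2), ignore_attr = TRUE)
})

test_that("FIML likelihood equals the brute-force density sum", {
  cp <- default_composite_cholesky_params()
  d <- simulate_cholesky_panel(cp, 40, 60, seed = 81)
  fit <- fit_cholesky(d, biv_vars, "AE", n_starts = 2)
  ## recompute the fitted -2lnL by summing per-pair MVN densities
  brute <- 0
  for (z in c("MZ", "DZ")) for (s1 in 0:1) for (s2 in 0:1) {
    sub <- d[d$zygosity == z & d$sex_t1 == s1 & d$sex_t2 == s2, , drop = FALSE]
    if (!nrow(sub)) next
    Y <- cbind(as.matrix(sub[, paste0(biv_vars, "_t1")]),
               as.matrix(sub[, paste0(biv_vars, "_t2")]))
    mom <- implied_pair_moments(fit$params, z, c(s1, s2))
    brute <- brute + mvn_neg2ll(Y, mom$mean, mom$Sigma)
  }
  expect_equal(fit$minus2lnL, brute, tolerance = 1e-8)

  ## missing data: observed sub-vector likelihood, same oracle
  dm <- apply_missingness(d, missingness_spec(c(0, 0, 0), 0.2), seed = 82)
  fitm <- fit_cholesky(dm, biv_vars, "AE", n_starts = 2)
  brute_m <- 0
  for (z in c("MZ", "DZ")) for (s1 in 0:1) for (s2 in 0:1) {
    sub <- dm[dm$zygosity == z & dm$sex_t1 == s1 & dm$sex_t2 == s2, , drop = FALSE]
    if (!nrow(sub)) next
    Y <- cbind(as.matrix(sub[, paste0(biv_vars, "_t1")]),
               as.matrix(sub[, paste0(biv_vars, "_t2")]))
    mom <- implied_pair_moments(fitm$params, z, c(s1, s2))
    brute_m <- brute_m + mvn_neg2ll(Y, mom$mean, mom$Sigma)
  }
  expect_equal(fitm$minus2lnL, brute_m, tolerance = 1e-8)
})

test_that("likelihood is invariant to within-pair twin order", {
  cp <- default_composite_cholesky_params()
  d <- simulate_cholesky_panel(cp, 150, 250, seed = 83)
  f1 <- fit_cholesky(d, biv_vars, "AE", n_starts = 2)
  f2 <- fit_cholesky(swap_twins(d), biv_vars, "AE", n_starts = 2)
  expect_equal(f1$minus2lnL, f2$minus2lnL, tolerance = 1e-6)
})

test_that("AE fit recovers generating components and sex means", {
  cp <- default_composite_cholesky_params()
  d <- simulate_cholesky_panel(cp, 1125, 1875, seed = 84)
  fit <- fit_cholesky(d, biv_vars, "AE")
  expect_true(fit$converged)
  vc <- variance_components(fit)
  expect_equal(unname(vc$a2), c(0.63, 0.57), tolerance = 0.05)
  expect_equal(unname(vc$a2 + vc$e2), c(1, 1), tolerance = 1e-8)
  expect_equal(vc$rA[1, 2], -0.513, tolerance = 0.08)
  expect_equal(unname(fit$params$means[, 2] - fit$params$means[, 1]),
               c(-0.3, 0.2), tolerance = 0.1)
  ## the two shared-percentage conventions agree near the symmetric truth
  vc_p <- variance_components(fit, shared_convention = "path")
  expect_equal(unname(vc_p$shared_pct_A), unname(vc$shared_pct_A),
               tolerance = 3)
  ## information-criterion identities
  expect_equal(fit$AIC, fit$minus2lnL + 2 * fit$n_params)
  expect_equal(fit$BIC, fit$minus2lnL + fit$n_params * log(fit$N))
})

test_that("model comparison respects nesting and flags the parsimonious model", {
  cp <- default_composite_cholesky_params()   # C = 0 generator
  d <- simulate_cholesky_panel(cp, 500, 800, seed = 85)
  ace <- fit_cholesky(d, biv_vars, "ACE", n_starts = 3)
  ae <- fit_cholesky(d, biv_vars, "AE", n_starts = 3)
  expect_gte(ae$minus2lnL, ace$minus2lnL - 1e-6)
  tab <- compare_models(ACE = ace, AE = ae)
  expect_equal(tab$dAIC[tab$model == "AE"], 0)
  ## identical fit twice: zero difference
  tab2 <- compare_models(AE = ae, AE2 = ae)
  expect_equal(tab2$dAIC, c(0, 0))
  ## fingerprint mismatch is an error
  d2 <- simulate_cholesky_panel(cp, 500, 800, seed = 86)
  ae2 <- fit_cholesky(d2, biv_vars, "AE", n_starts = 2)
  expect_error(compare_models(ae, ae2), "identical data")
})

test_that("null genetic correlation yields near-zero shared percentage", {
  A <- diag(c(0.6, 0.5)); E <- diag(c(0.4, 0.5))
  cp <- cholesky_params(a = t(chol(A)), e = t(chol(E)), variables = biv_vars)
  d <- simulate_cholesky_panel(cp, 1000, 1600, seed = 87)
  vc <- variance_components(fit_cholesky(d, biv_vars, "AE"))
  expect_lt(vc$shared_pct_A[1], 2)
})

test_that("single-group data is rejected (A and C not separable)", {
  cp <- default_composite_cholesky_params()
  d <- simulate_cholesky_panel(cp, 100, 0, seed = 88)
  expect_error(fit_cholesky(d, biv_vars, "ACE"), "zygosity")
})
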