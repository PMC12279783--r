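# Shared fixtures: small parameter sets and panels built in code.

tiny_riclpm_params <- function(...) {
  base <- default_riclpm_params()
  args <- list(...)
  for (nm in names(args)) base[[nm]] <- args[[nm]]
  do.call(riclpm_params, base[setdiff(names(base), character())])
}

# univariate AE Cholesky parameters at heritability a2 (unit total variance)
univ_ae_params <- function(a2, variable = "psychopathology_1",
                           sex_means = c(0, 0)) {
  cholesky_params(a = matrix(sqrt(a2), 1, 1), e = matrix(sqrt(1 - a2), 1, 1),
                  means = cbind(sex_means[1], sex_means[2]),
                  variables = variable)
}

# Monte-Carlo standard error of a covariance entry under normality
cov_mc_se <- function(Sigma, n) {
  sqrt((outer(diag(Sigma), diag(Sigma)) + Sigma^2) / n)
}

# family-wise threshold equivalent to a single two-sided 3-SE comparison,
# Sidak-adjusted for the number of entries compared
sidak_z <- function(n_entries, z_single = 3) {
  alpha <- 2 * stats::pnorm(-z_single)
  stats::qnorm(1 - (1 - (1 - alpha)^(1 / n_entries)) / 2)
}

# pair-level 12-column matrix for one zygosity group (test-side shortcut)
pair_matrix_12 <- function(panel, zygosity) {
  sub <- panel[panel$zygosity == zygosity, , drop = FALSE]
  sub <- twin_panel(sub, attr(panel, "traits"), attr(panel, "waves"))
  cbind(panel_matrix(sub, 1), panel_matrix(sub, 2))
}
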