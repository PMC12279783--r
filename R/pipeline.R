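## Configuration-driven orchestration of the full analysis chain on
## simulated (or supplied) twin data.

#' Default pipeline configuration
#'
#' Study-calibrated generating parameters ([default_riclpm_params()],
#' [default_measurement_params()], [default_missingness_spec()]), the
#' reference sample composition (577 MZ / 961 DZ pairs), ten imputation
#' chains with ten sweeps, and all stages enabled.
#'
#' @param seed master seed (every stochastic stage derives its stream from
#'   it).
#' @param n_mz,n_dz pair counts.
#' @return a list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L, n_mz = 577L, n_dz = 961L) {
  structure(list(
    seed = as.integer(seed), n_mz = as.integer(n_mz), n_dz = as.integer(n_dz),
    riclpm = default_riclpm_params(),
    measurement = default_measurement_params(),
    missingness = default_missingness_spec(),
    impute = list(n_imputations = 10L, n_iterations = 10L),
    trait_specs = default_trait_specs(),
    stages = c("simulate", "indicators", "missingness", "impute", "measure",
               "residualize", "correlate", "cholesky", "riclpm", "composite",
               "bivariate"),
    tolerances = list(rA_ri = 0.07, A_share_ri = 0.06, ri_share = 0.05,
                      crosslag_std = 0.04)),
    class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order (each stage optional via `config$stages`):
#' simulation of latent general-factor scores under the biometric RI-CLPM;
#' indicator generation; missingness masking; chained-equation imputation;
#' general-factor measurement models and factor scores;
#' sex residualization; phenotypic and cross-twin correlations; trivariate
#' Cholesky ACE vs AE comparison per trait; the biometric RI-CLPM with fit
#' indices, cross-lag likelihood-ratio tests and derived stability;
#' cross-wave composite aggregation; and the bivariate Cholesky AE
#' decomposition of the composites.  Every stage is timed and logged; with
#' `out_dir` set, tables (CSV/TSV) and a machine-readable results JSON are
#' written as stages complete, so a failed run preserves partial outputs.
#'
#' @param config a [default_pipeline_config()]-style list.
#' @param out_dir optional output directory.
#' @param data optional externally supplied [twin_panel()] of factor-level
#'   scores; skips the simulation stages.
#' @param verbose print stage progress.
#' @return a list with the intermediate panels, fitted objects, tables and a
#'   stage `log` data frame.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL,
                         data = NULL, verbose = TRUE) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  res <- list(config = config)
  log <- data.frame(stage = character(), seconds = numeric(),
                    status = character(), stringsAsFactors = FALSE)
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    if (!name %in% config$stages) {
      log[nrow(log) + 1L, ] <<- list(name, 0, "skipped")
      return(invisible(NULL))
    }
    t0 <- proc.time()[3L]
    say("stage ", name, " ...")
    out <- force(expr)
    log[nrow(log) + 1L, ] <<- list(name, round(proc.time()[3L] - t0, 2), "ok")
    if (!is.null(out_dir))
      utils::write.table(log, file.path(out_dir, "stage_log.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    out
  }
  seed <- config$seed
  specs <- config$trait_specs

  if (is.null(data)) {
    res$truth <- stage("simulate",
      simulate_riclpm_panel(config$riclpm, config$n_mz, config$n_dz,
                            seed = seed))
    res$indicators <- stage("indicators",
      if (!is.null(res$truth))
        emit_indicators(res$truth, config$measurement, seed = seed + 1000L))
    if (!is.null(res$indicators)) {
      masked <- stage("missingness",
        apply_missingness(res$indicators, config$missingness,
                          seed = seed + 2000L))
      if (is.null(masked)) masked <- res$indicators
      res$observed <- masked
    }
  } else {
    res$observed <- data
  }

  if (!is.null(res$observed) && length(tp_traits(res$observed)) > 2L) {
    ## indicator-level data: impute, measure, score
    res$imputed <- stage("impute",
      impute_fcs(res$observed, config$impute$n_imputations,
                 config$impute$n_iterations, seed = seed + 3000L))
    if (is.null(res$imputed)) res$imputed <- res$observed
    meas <- stage("measure", {
      fits <- lapply(specs, function(sp) fit_general_factor(res$imputed, sp))
      sc <- lapply(fits, function(f) factor_scores(f, res$imputed))
      scores <- sc[[1L]]
      for (i in seq_along(sc)[-1L]) {
        add <- sc[[i]]
        scores <- cbind(scores,
                        add[, setdiff(names(add), names(scores)), drop = FALSE])
      }
      scores <- twin_panel(scores, traits = names(fits),
                           waves = tp_waves(res$imputed))
      list(fits = fits, scores = scores)
    })
    if (!is.null(meas)) {
      res$factor_fits <- meas$fits
      res$scores <- meas$scores
      if (!is.null(out_dir)) write_loadings_tsv(meas$fits, out_dir)
    }
  } else {
    res$scores <- res$observed
  }

  if (!is.null(res$scores)) {
    traits <- tp_traits(res$scores)
    res$residualized <- stage("residualize", residualize_on_sex(res$scores))
    res$correlations <- stage("correlate", {
      rep <- phenotypic_correlations(res$scores)
      rep <- cross_twin_correlations(res$scores, "MZ", rep)
      rep <- cross_twin_correlations(res$scores, "DZ", rep)
      if (!is.null(out_dir)) {
        utils::write.table(rep$phenotypic,
                           file.path(out_dir, "phenotypic_correlations.tsv"),
                           sep = "\t", quote = FALSE)
        for (z in c("MZ", "DZ"))
          utils::write.table(rep$cross_twin[[z]],
                             file.path(out_dir,
                                       paste0("cross_twin_", z, ".tsv")),
                             sep = "\t", quote = FALSE)
      }
      rep
    })
    res$cholesky <- stage("cholesky", {
      out <- list()
      for (trait in traits) {
        vars <- paste0(trait, "_", tp_waves(res$scores))
        ace <- fit_cholesky(res$scores, vars, "ACE")
        ae <- fit_cholesky(res$scores, vars, "AE")
        out[[trait]] <- list(ACE = ace, AE = ae,
                             comparison = compare_models(ACE = ace, AE = ae))
      }
      if (!is.null(out_dir)) {
        cmp <- do.call(rbind, lapply(names(out), function(tr)
          cbind(trait = tr, out[[tr]]$comparison)))
        utils::write.table(cmp, file.path(out_dir, "cholesky_comparison.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      }
      out
    })
    rdata <- if (!is.null(res$residualized)) res$residualized else res$scores
    res$riclpm <- stage("riclpm", {
      fit <- fit_riclpm(rdata)
      list(fit = fit,
           indices = fit_indices(fit),
           cross_lags = test_cross_lags(rdata, fit),
           stability = derived_stability(fit))
    })
    if (!is.null(res$riclpm) && !is.null(out_dir)) {
      utils::write.table(res$riclpm$cross_lags,
                         file.path(out_dir, "cross_lag_tests.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      jsonlite::write_json(
        riclpm_estimates_list(res$riclpm),
        file.path(out_dir, "riclpm_estimates.json"),
        auto_unbox = TRUE, digits = NA)
    }
    res$composites <- stage("composite", aggregate_composite(res$scores))
    res$bivariate <- stage("bivariate", {
      comp <- if (!is.null(res$composites)) res$composites else res$scores
      vars <- paste0(tp_traits(comp), "_", tp_waves(comp)[1L])
      fit <- fit_cholesky(comp, vars, "AE")
      list(fit = fit, components = variance_components(fit))
    })
  }
  res$log <- log
  if (!is.null(out_dir))
    jsonlite::write_json(pipeline_results_list(res),
                         file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA)
  res
}

write_loadings_tsv <- function(fits, out_dir) {
  rows <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(factor = nm, indicator = names(f$lambda),
               loading = unname(f$lambda),
               explained_variance = f$explained_variance,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, file.path(out_dir, "factor_loadings.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
}

riclpm_estimates_list <- function(r) {
  st <- r$stability
  list(minus2lnL = r$fit$minus2lnL, AIC = r$fit$AIC, BIC = r$fit$BIC,
       CFI = r$indices$CFI, TLI = r$indices$TLI, RMSEA = r$indices$RMSEA,
       rA_ri = st$rA_ri, rE_ri = st$rE_ri,
       A_share_ri = as.list(st$A_share_ri),
       ri_share = apply(st$ri_share, 1L, as.list),
       theta = as.list(r$fit$theta))
}

pipeline_results_list <- function(res) {
  out <- list(seed = res$config$seed,
              n_mz = res$config$n_mz, n_dz = res$config$n_dz)
  if (!is.null(res$factor_fits))
    out$loadings <- lapply(res$factor_fits, function(f) as.list(f$lambda))
  if (!is.null(res$riclpm)) out$riclpm <- riclpm_estimates_list(res$riclpm)
  if (!is.null(res$cholesky))
    out$cholesky <- lapply(res$cholesky, function(x)
      list(AIC_ACE = x$ACE$AIC, AIC_AE = x$AE$AIC,
           BIC_ACE = x$ACE$BIC, BIC_AE = x$AE$BIC,
           a2_AE = as.list(variance_components(x$AE)$a2)))
  if (!is.null(res$bivariate))
    out$bivariate <- list(
      a2 = as.list(res$bivariate$components$a2),
      e2 = as.list(res$bivariate$components$e2),
      shared_pct_A = as.list(res$bivariate$components$shared_pct_A),
      shared_pct_E = as.list(res$bivariate$components$shared_pct_E))
  ## wall times are environment-dependent; keep them out of the results JSON
  ## so runs under a fixed seed are byte-identical
  out$stages <- if (!is.null(res$log)) res$log[, c("stage", "status")] else NULL
  out
}

#' Compare generating values with pipeline estimates
#'
#' Builds a side-by-side recovery table for the quantities the generating
#' configuration pins down: the RI genetic correlation, A shares of RI
#' variance, RI variance shares per trait and wave, and the standardized
#' cross-lagged path, each with absolute error and a pass flag against the
#' configured tolerance.
#'
#' @param truth the [default_pipeline_config()]-style configuration the data
#'   were generated from.
#' @param results the [run_pipeline()] result computed on those data.
#' @return data frame with columns `quantity`, `truth`, `estimate`,
#'   `abs_error`, `tolerance`, `pass` (`NA` for stages not evaluated).
#' @export
recovery_report <- function(truth, results) {
  if (!is.null(results$config) &&
      !identical(results$config$seed, truth$seed))
    stop("recovery_report: results were not produced under this config seed")
  ts <- derived_stability(truth$riclpm)
  tol <- truth$tolerances
  rows <- list()
  add <- function(q, tv, ev, tl) rows[[length(rows) + 1L]] <<-
    data.frame(quantity = q, truth = tv, estimate = ev,
               abs_error = abs(ev - tv), tolerance = tl,
               pass = if (is.na(ev)) NA else abs(ev - tv) <= tl,
               stringsAsFactors = FALSE)
  es <- if (!is.null(results$riclpm)) results$riclpm$stability else NULL
  get <- function(f) if (is.null(es)) NA_real_ else f(es)
  add("rA_ri", ts$rA_ri, get(function(e) e$rA_ri), tol$rA_ri)
  for (k in 1:2) {
    tr <- truth$riclpm$traits[k]
    add(paste0("A_share_ri.", tr), ts$A_share_ri[k],
        get(function(e) e$A_share_ri[k]), tol$A_share_ri)
    for (w in 1:3)
      add(paste0("ri_share.", tr, ".w", w), ts$ri_share[k, w],
          get(function(e) e$ri_share[k, w]), tol$ri_share)
  }
  add("crosslag_std.w2_w3", ts$std_paths$w2_to_w3[2, 1],
      get(function(e) e$std_paths$w2_to_w3[2, 1]), tol$crosslag_std)
  do.call(rbind, rows)
}

## ---- config serialization --------------------------------------------------

plain_mat <- function(m) list(data = as.vector(m), nrow = nrow(m),
                              ncol = ncol(m))
unplain_mat <- function(l) matrix(unlist(l$data), l$nrow, l$ncol)

#' Write / read a pipeline configuration (YAML or JSON)
#'
#' Round-trips the full configuration, including all generator parameter
#' matrices, through a plain-text file; format chosen by extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param config a `pipeline_config`.
#' @param path file path.
#' @return `read_pipeline_config` returns the reconstructed config.
#' @export
write_pipeline_config <- function(config, path) {
  r <- config$riclpm
  plain <- list(
    seed = config$seed, n_mz = config$n_mz, n_dz = config$n_dz,
    riclpm = c(lapply(r[c("VA_ri", "VE_ri", "B1", "B2", "SA_w1", "SE_w1",
                          "SA_u2", "SE_u2", "SA_u3", "SE_u3", "mu")],
                      plain_mat),
               list(sex_effect = r$sex_effect, traits = r$traits)),
    measurement = lapply(config$measurement, function(mp)
      list(loadings = as.list(mp$loadings),
           uniqueness = plain_mat(mp$uniqueness))),
    missingness = list(wave_dropout = config$missingness$wave_dropout,
                       cell_mcar = config$missingness$cell_mcar),
    impute = config$impute,
    stages = config$stages,
    tolerances = config$tolerances)
  if (grepl("\\.json$", path))
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(plain, path, precision = 15L)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  plain <- if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  r <- plain$riclpm
  mats <- lapply(r[c("VA_ri", "VE_ri", "B1", "B2", "SA_w1", "SE_w1",
                     "SA_u2", "SE_u2", "SA_u3", "SE_u3", "mu")], unplain_mat)
  cfg <- default_pipeline_config(plain$seed, plain$n_mz, plain$n_dz)
  cfg$riclpm <- riclpm_params(
    VA_ri = mats$VA_ri, VE_ri = mats$VE_ri, B1 = mats$B1, B2 = mats$B2,
    SA_w1 = mats$SA_w1, SE_w1 = mats$SE_w1, SA_u2 = mats$SA_u2,
    SE_u2 = mats$SE_u2, SA_u3 = mats$SA_u3, SE_u3 = mats$SE_u3,
    mu = mats$mu, sex_effect = unlist(r$sex_effect),
    traits = unlist(r$traits))
  cfg$measurement <- lapply(plain$measurement, function(mp) {
    lam <- unlist(mp$loadings)
    measurement_params(lam, unplain_mat(mp$uniqueness))
  })
  cfg$missingness <- missingness_spec(unlist(plain$missingness$wave_dropout),
                                      plain$missingness$cell_mcar)
  cfg$impute <- lapply(plain$impute, as.integer)
  cfg$stages <- unlist(plain$stages)
  cfg$tolerances <- lapply(plain$tolerances, as.numeric)
  cfg
}
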