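#' Longitudinal twin-pair panel data
#'
#' A `twin_panel` is a data frame with one row per twin pair holding zygosity,
#' per-twin sex, and per-twin phenotype scores for a set of traits measured at
#' one or more waves.  Phenotype columns are named `<trait>_<wave>_t<1|2>`;
#' missing entries are `NA`.  Pairs are the sampling unit: all model fitting in
#' the package consumes this wide one-row-per-pair layout directly.
#'
#' Sex is coded 0 = male, 1 = female.  Twin order within a pair carries no
#' information; estimators in this package are invariant to swapping the two
#' slots (see [swap_twins()]).
#'
#' @param pairs data frame with columns `pair_id`, `zygosity` (`"MZ"`/`"DZ"`),
#'   `sex_t1`, `sex_t2` (0/1), plus one `<trait>_<wave>_t<twin>` column per
#'   trait/wave/twin combination.
#' @param traits character vector of trait labels.
#' @param waves integer vector of wave labels (default `1:3`).
#' @return an object of class `twin_panel` (a data frame with `traits` and
#'   `waves` attributes).
#' @seealso [read_twin_csv()], [simulate_riclpm_panel()],
#'   [simulate_cholesky_panel()]
#' @export
twin_panel <- function(pairs, traits, waves = 1:3) {
  stopifnot(is.data.frame(pairs), length(traits) >= 1L, length(waves) >= 1L)
  needed <- c("pair_id", "zygosity", "sex_t1", "sex_t2",
              tp_score_cols(traits, waves))
  miss <- setdiff(needed, names(pairs))
  if (length(miss))
    stop("twin_panel: missing mandatory columns: ", paste(miss, collapse = ", "))
  bad <- !pairs$zygosity %in% c("MZ", "DZ")
  if (any(bad))
    stop("twin_panel: unknown zygosity code for pair_id(s): ",
         paste(utils::head(pairs$pair_id[bad], 10L), collapse = ", "))
  badsex <- vapply(c("sex_t1", "sex_t2"), function(cn)
    any(!is.na(pairs[[cn]]) & !pairs[[cn]] %in% c(0, 1)), logical(1))
  if (any(badsex)) stop("twin_panel: sex must be coded 0 (male) / 1 (female)")
  out <- pairs[, needed, drop = FALSE]
  for (cn in tp_score_cols(traits, waves)) out[[cn]] <- as.numeric(out[[cn]])
  structure(out, traits = as.character(traits), waves = as.integer(waves),
            class = c("twin_panel", "data.frame"))
}

tp_traits <- function(x) attr(x, "traits")
tp_waves  <- function(x) attr(x, "waves")

## variable labels "<trait>_<wave>" in canonical order: wave-major, trait-minor
## (this ordering is shared with the implied-moment builders)
tp_vars <- function(traits, waves) {
  as.vector(t(outer(waves, traits, function(w, k) paste0(k, "_", w))))
}

tp_score_cols <- function(traits, waves, twin = 1:2) {
  unlist(lapply(twin, function(tw) paste0(tp_vars(traits, waves), "_t", tw)))
}

#' Extract per-twin score matrices from a twin panel
#'
#' @param x a [twin_panel()].
#' @param twin which twin slot (1 or 2).
#' @return numeric matrix, one row per pair, columns `<trait>_<wave>` in
#'   wave-major order.
#' @export
panel_matrix <- function(x, twin = 1L) {
  vars <- tp_vars(tp_traits(x), tp_waves(x))
  m <- as.matrix(x[, paste0(vars, "_t", twin), drop = FALSE])
  colnames(m) <- vars
  storage.mode(m) <- "double"
  m
}

#' @rdname panel_matrix
#' @details `individual_matrix` stacks both twins (twin 1 rows first) for
#'   analyses that pool individuals; `individual_sex` returns the matching
#'   sex vector.
#' @export
individual_matrix <- function(x) rbind(panel_matrix(x, 1L), panel_matrix(x, 2L))

#' @rdname panel_matrix
#' @export
individual_sex <- function(x) c(x$sex_t1, x$sex_t2)

## write a full 2n x p individual matrix back into the pair layout
set_individual_matrix <- function(x, m) {
  n <- nrow(x)
  vars <- tp_vars(tp_traits(x), tp_waves(x))
  stopifnot(nrow(m) == 2L * n, ncol(m) == length(vars))
  for (j in seq_along(vars)) {
    x[[paste0(vars[j], "_t1")]] <- m[seq_len(n), j]
    x[[paste0(vars[j], "_t2")]] <- m[n + seq_len(n), j]
  }
  x
}

#' Swap the two twin slots of every pair
#'
#' Downstream estimators are invariant to within-pair order; this helper is
#' used to verify that property.
#' @param x a [twin_panel()].
#' @return the panel with twin 1 and twin 2 exchanged.
#' @export
swap_twins <- function(x) {
  vars <- tp_vars(tp_traits(x), tp_waves(x))
  out <- x
  out$sex_t1 <- x$sex_t2
  out$sex_t2 <- x$sex_t1
  for (v in vars) {
    out[[paste0(v, "_t1")]] <- x[[paste0(v, "_t2")]]
    out[[paste0(v, "_t2")]] <- x[[paste0(v, "_t1")]]
  }
  out
}

#' @export
print.twin_panel <- function(x, ...) {
  cat("Twin panel: ", nrow(x), " pairs (",
      sum(x$zygosity == "MZ"), " MZ, ", sum(x$zygosity == "DZ"), " DZ)\n",
      "  traits: ", paste(tp_traits(x), collapse = ", "), "\n",
      "  waves:  ", paste(tp_waves(x), collapse = ", "), "\n", sep = "")
  nm <- sum(is.na(as.matrix(x[, tp_score_cols(tp_traits(x), tp_waves(x))])))
  cat("  missing score cells: ", nm, "\n", sep = "")
  invisible(x)
}

#' Read a twin panel from CSV
#'
#' Expects the wide pair-level layout written by [write_twin_csv()]: columns
#' `pair_id`, `zygosity`, `sex_t1`, `sex_t2`, then `<trait>_<wave>_t<1|2>`.
#' Trait and wave labels are inferred from the header unless given.
#' Unparseable numeric cells become missing; a count is reported via `message`.
#'
#' @param path CSV file path.
#' @param traits,waves optional explicit labels; inferred from the header when
#'   `NULL`.
#' @return a [twin_panel()].
#' @export
read_twin_csv <- function(path, traits = NULL, waves = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  for (cn in c("pair_id", "zygosity", "sex_t1", "sex_t2"))
    if (!cn %in% names(df)) stop("read_twin_csv: missing mandatory column ", cn)
  sc <- grep("^(.*)_([0-9]+)_t([12])$", names(df), value = TRUE)
  m <- regmatches(sc, regexec("^(.*)_([0-9]+)_t([12])$", sc))
  tr <- vapply(m, `[`, "", 2L)
  wv <- as.integer(vapply(m, `[`, "", 3L))
  if (is.null(traits)) traits <- unique(tr)
  if (is.null(waves))  waves <- sort(unique(wv))
  n_bad <- 0L
  for (cn in sc) {
    v <- df[[cn]]
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    n_bad <- n_bad + sum(!is.na(v) & is.na(num))
    df[[cn]] <- num
  }
  if (n_bad > 0L)
    message("read_twin_csv: ", n_bad, " unparseable numeric cell(s) set to missing")
  df$sex_t1 <- suppressWarnings(as.integer(df$sex_t1))
  df$sex_t2 <- suppressWarnings(as.integer(df$sex_t2))
  twin_panel(df, traits = traits, waves = waves)
}

#' Write a twin panel to CSV
#'
#' Missing cells are written as empty fields.  `read_twin_csv(write_twin_csv(x))`
#' reproduces values and missingness exactly (up to float formatting at 15
#' significant digits).
#'
#' @param data a [twin_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_twin_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Regress sex out of phenotype columns
#'
#' Replaces each named variable by the residuals of an ordinary least-squares
#' regression of that variable on sex (0 = male, 1 = female), fitted over all
#' individual twins pooled.  Residuals have mean zero; the operation is
#' idempotent.  Pre-processing step before the RI-CLPM, which estimates a
#' single mean per variable.
#'
#' @param data a [twin_panel()]; sex must be observed for every twin whose
#'   scores are used.
#' @param traits traits to residualize (default: all).
#' @return the panel with the selected score columns replaced by residuals.
#' @export
residualize_on_sex <- function(data, traits = tp_traits(data)) {
  sex <- individual_sex(data)
  m <- individual_matrix(data)
  vars <- tp_vars(tp_traits(data), tp_waves(data))
  sel <- vapply(strsplit(vars, "_(?=[0-9]+$)", perl = TRUE), `[`, "", 1L) %in% traits
  for (j in which(sel)) {
    y <- m[, j]
    ok <- !is.na(y)
    if (!any(ok)) stop("residualize_on_sex: variable all missing: ", vars[j])
    if (any(is.na(sex[ok]))) stop("residualize_on_sex: sex missing for twins with observed ", vars[j])
    fit <- stats::lm.fit(cbind(1, sex[ok]), y[ok])
    m[ok, j] <- fit$residuals
  }
  set_individual_matrix(data, m)
}

#' Trait specification for a general factor
#'
#' Names the indicator scales that load on one general factor and the anchor
#' indicator that fixes the factor's sign (the anchor loads positively).
#'
#' @param name factor label, e.g. `"psychopathology"`.
#' @param indicators ordered character vector of indicator scale labels.
#' @param anchor indicator used to orient the factor sign (default: first).
#' @param reverse_keyed indicators expected to load negatively (informational).
#' @return an object of class `trait_spec`.
#' @export
trait_spec <- function(name, indicators, anchor = indicators[1L],
                       reverse_keyed = character()) {
  stopifnot(length(indicators) >= 1L, anchor %in% indicators,
            all(reverse_keyed %in% indicators))
  structure(list(name = name, indicators = indicators, anchor = anchor,
                 reverse_keyed = reverse_keyed), class = "trait_spec")
}

#' Built-in trait specifications
#'
#' The two general factors used throughout: a general factor of personality
#' over the Big Five traits (neuroticism reverse-keyed, extraversion anchor)
#' and a general factor of psychopathology over seven symptom scales
#' (depressive symptoms anchor).
#' @return a named list of two [trait_spec()] objects.
#' @export
default_trait_specs <- function() {
  list(
    personality = trait_spec(
      "personality",
      c("neuroticism", "extraversion", "openness", "agreeableness",
        "conscientiousness"),
      anchor = "extraversion", reverse_keyed = "neuroticism"),
    psychopathology = trait_spec(
      "psychopathology",
      c("depressive", "anxiety", "somatic", "eating", "delinquency",
        "conduct", "substance"),
      anchor = "depressive")
  )
}
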