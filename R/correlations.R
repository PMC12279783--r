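## Descriptive layer: phenotypic stability/cross-trait correlations and
## double-entry cross-twin correlations by zygosity.

#' Phenotypic correlations across traits and waves
#'
#' Pearson correlations over all individual twins pooled, pairwise-complete.
#'
#' @param scores a [twin_panel()] (typically factor scores).
#' @return an object of class `twin_correlations` holding the `phenotypic`
#'   correlation matrix and `n_phenotypic`, the effective n per cell.
#' @export
phenotypic_correlations <- function(scores) {
  X <- individual_matrix(scores)
  C <- stats::cor(X, use = "pairwise.complete.obs")
  N <- crossprod(!is.na(X))
  C[N < 3L] <- NA_real_
  structure(list(phenotypic = C, n_phenotypic = N,
                 cross_twin = list(), n_cross_twin = list()),
            class = "twin_correlations")
}

#' Cross-twin correlations by zygosity (double entry)
#'
#' Correlations between twin-1 and twin-2 variables within a zygosity group,
#' computed double entry: each pair contributes in both twin orders, which
#' makes the estimator exactly invariant to within-pair order.  The diagonal
#' holds the cross-twin within-trait correlations; off-diagonal cells are
#' cross-twin cross-trait correlations.
#'
#' @param scores a [twin_panel()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param report optional `twin_correlations` object to extend.
#' @return a `twin_correlations` object with the group's matrix under
#'   `cross_twin[[zygosity]]` (and pair counts in `n_cross_twin`).
#' @export
cross_twin_correlations <- function(scores, zygosity,
                                    report = phenotypic_correlations(scores)) {
  if (!zygosity %in% c("MZ", "DZ"))
    stop("cross_twin_correlations: unknown zygosity ", zygosity)
  sub <- scores[scores$zygosity == zygosity, , drop = FALSE]
  sub <- twin_panel(sub, tp_traits(scores), tp_waves(scores))
  X1 <- panel_matrix(sub, 1L); X2 <- panel_matrix(sub, 2L)
  A <- rbind(X1, X2); B <- rbind(X2, X1)
  C <- stats::cor(A, B, use = "pairwise.complete.obs")
  Np <- (crossprod(!is.na(X1), !is.na(X2)) +
           crossprod(!is.na(X2), !is.na(X1))) / 2
  C[Np < 3L] <- NA_real_
  report$cross_twin[[zygosity]] <- C
  report$n_cross_twin[[zygosity]] <- Np
  report
}

#' @export
print.twin_correlations <- function(x, digits = 2, ...) {
  cat("Phenotypic correlations (pooled individuals, pairwise complete):\n")
  print(round(x$phenotypic, digits))
  for (z in names(x$cross_twin)) {
    cat("\nCross-twin correlations, ", z, " (double entry):\n", sep = "")
    print(round(x$cross_twin[[z]], digits))
  }
  invisible(x)
}
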