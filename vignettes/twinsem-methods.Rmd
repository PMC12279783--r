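---
title: "Methods: biometric twin models for co-developing general factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biometric twin models for co-developing general factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models twinsem implements, the assumptions they
make, the calibration of the synthetic-data generators, and the numerical
and design choices a maintainer would want spelled out.  Nothing here states
an empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The biometric RI-CLPM

Two traits (a general personality factor and a general psychopathology
factor) are observed at three waves on both members of MZ and DZ twin
pairs.  Each observation decomposes as

$$y_{jkt} = \mu_{kt} + \mathrm{RI}_{jk} + w_{jkt},$$

a trait- and wave-specific mean, a time-invariant random intercept, and a
within-person deviation.  The within-person process follows first-order
dynamics $w_{j\cdot,t+1} = B_t\, w_{j\cdot t} + u_{j\cdot,t+1}$ with
interval-specific $2\times2$ path matrices (diagonal entries: autoregression,
the persistence of within-person deviations; off-diagonal entries:
cross-lagged paths, the influence of one trait's deviation on the other
trait one wave later).

The genetically informative extension splits the random intercepts, the
wave-1 within-person component, and each innovation into additive-genetic
(A) and non-shared-environment (E) parts.  A parts correlate 1 between MZ
co-twins and 0.5 between DZ co-twins — the standard biometric assumption,
applied to *every* A stream; E parts are twin-specific.  Both streams pass
through the same $B_t$: the model has one within-person process per
observation, observed as an A+E mixture.  The alternative (separate
dynamics for A and E deviations) doubles the path parameters, is poorly
identified with three waves, and was rejected for parsimony.

Shared environment (C) is deliberately absent from the RI-CLPM: the twin
correlation pattern this model family targets (DZ correlations about half
the MZ correlations) carries no C signal, and C-in-RI-CLPM is weakly
identified at these sample sizes.  The Cholesky module retains full ACE so
the AE restriction is testable there.

Assumptions worth stating: multivariate normality of all components;
random mating and no gene–environment correlation or interaction (the usual
ACE identification conditions); equal environments across zygosity; DZ
genetic correlation exactly 0.5 (opposite-sex DZ pairs are pooled with
same-sex DZ pairs; sex enters only through means); missingness ignorable
given the observed data (MAR) for FIML.

### Implied moments and likelihood

With wave-major variable ordering, the within-twin covariance is
$\Sigma_w = \mathbf{1}_{3\times3}\otimes(V^A_{RI}+V^E_{RI}) + W_A + W_E$,
where $W_X$ propagates the wave-1 covariance and innovations of stream $X$
through $B_1, B_2$; the cross-twin block is
$r\,(\mathbf{1}\otimes V^A_{RI} + W_A)$ with $r = 1$ (MZ) or $0.5$ (DZ).
Pairs are grouped by zygosity and missingness pattern; within a pattern the
two-group FIML deviance depends on the data only through the pattern's
count, mean and scatter, so one likelihood evaluation costs two $12\times12$
Cholesky factorizations per pattern regardless of sample size.  The kernels
are compiled (RcppArmadillo); an R-level brute-force per-pair density sum
(`mvn_neg2ll()`) serves as an independent oracle and agrees to machine
precision in the tests, with and without missing data.

### Parameters, counts, fit indices

The fit estimates 38 parameters: 8 covariance blocks × 3 (two log
variances, one atanh correlation each), 8 path entries, 6 means (means are
common across twins, sexes and groups because inputs are sex-residualized
scores).  The saturated two-group model has 180 moments, so the model χ²
has 142 df.  The baseline model frees means and variances per group with
zero covariances (48 parameters, 132 df).  Conventions, which differ across
SEM software and are therefore fixed explicitly here: the saturated model
with missing data is estimated by a per-group EM algorithm (closed form
when complete); RMSEA uses the multi-group scaling
$\sqrt{G\,\max(\chi^2_M - df_M, 0)/(df_M\,N)}$ with $G = 2$ groups and $N$
the total number of pairs; TLI is capped at 1; BIC uses $N$ = number of
pairs — pairs, not individuals, are the independent sampling units.

### Optimization

BFGS (`stats::optim`) on the unconstrained scale with central-difference
gradients, relative tolerance $10^{-12}$, one moment-based start plus
jittered restarts (default 3; the start derives random-intercept and
within-process blocks from averaged cross-wave covariance blocks and an
A-fraction from the MZ/DZ cross-twin contrast).  Variance parameters live
on the log scale, so zero-variance solutions appear as large negative
log-variances (boundary behavior is visible in the estimates, e.g. an RI
E-correlation pinned at ±1 in very small samples).  Cross-lag tests refit
with one path fixed at zero, warm-started from the full fit; χ² differences
are floored at zero.

## 2. Cholesky ACE/AE decomposition

`A = aa'`, `C = cc'`, `E = ee'` with lower-triangular paths keeps all three
PSD by construction; E is effectively positive definite in practice since it
absorbs measurement error.  Means are sex-specific per variable (the only
sex effect modeled; sex-limitation of path coefficients is out of scope).
Starting values are Falconer-style moment estimates
($A_0 = 2(C_{MZ}-C_{DZ})$ etc., eigenvalue-floored), five optimizer starts
by default.  Standardized components divide by the fitted total variance,
so $a^2 + c^2 + e^2 = 1$ holds identically.

For bivariate fits the shared genetic percentage is reported as
$100\,r_A^2$ — symmetric in the two traits — rather than the order-dependent
Cholesky path share $100\,a_{21}^2/(a_{21}^2+a_{22}^2)$; reference analyses
that report slightly asymmetric shared percentages for the two traits are
using the path convention in both variable orders.  Both conventions are
available (`variance_components(..., shared_convention = "path")`), and they
coincide exactly for the second-ordered trait.

## 3. Measurement stage

Indicators are z-scored over all pooled individuals before factor analysis
because the constituent scales have heterogeneous ranges (0–3 up to 0–6
in the instruments this emulates).  The general-factor model is a
correlated three-factor ML fit (one factor per wave, factor variances 1,
free inter-wave correlations) with each indicator's loading constrained
equal across waves — the equality is imposed by parameterization, so the
fitted loadings are bit-identical across waves, matching the design in
which cross-wave change is attributed to the factor, not to shifting
loadings.  Uniquenesses are free per wave and kept positive on the log
scale; values driven to ~0 are reported with a Heywood warning.  The factor
sign is fixed by an anchor indicator (extraversion for personality, so
neuroticism loads negatively; depressive symptoms for psychopathology, so
the factor is problem-load positive).

One identifiability caveat, exercised by the tests: when the factors carry
no common covariance (all true loadings zero), individual loadings are not
identified — one loading can grow while the inter-wave correlations shrink
to zero along a likelihood ridge.  The identified quantity is the implied
common covariance $\Lambda\Phi\Lambda'$, and that is what the degenerate
test asserts vanishes.

Factor scores are regression (Thurstone) scores
$\hat f = \Phi\Lambda'\Sigma^{-1}x$ from the model-implied covariance,
restricted to each individual's observed indicator sub-vector; a wave with
no observed indicators yields a missing score.  For a single unit-variance
factor this reduces to the textbook $\Lambda'\Sigma^{-1}x$.

Imputation is individual-level FCS with ridge-stabilized linear models and
residual draws, swept 10 times per chain, 10 chains, and the cell-wise
*mean* of the completed datasets is returned — matching a design in which
mean scores feed the factor analyses.  A consequence the tests document:
averaging chains moves imputed cells toward conditional means, which
slightly inflates the strongest correlations (observed ~0.05 at 20% MCAR
versus ~0.02 for a single stochastic chain).  Downstream twin models do not
depend on this: they use FIML on their own inputs.

Cross-wave composites are one-factor fits to a trait's three wave scores
(free loadings — with three indicators the model is just-identified), with
regression scores as the composite; individuals with fewer than two
observed waves get a missing composite, and near-independent wave scores
(all inter-wave correlations below 0.1) trigger a degeneracy warning.

## 4. Descriptive correlations

Phenotypic correlations pool both twins, pairwise-complete.  Cross-twin
correlations are double entry: each pair contributes in both twin orders,
making the estimator exactly invariant to the arbitrary within-pair
ordering (enforced by a test).  Pairwise-complete deletion is deliberate
here — the descriptive layer should not depend on the imputation model;
model-based stages handle missingness by FIML.

## 5. Synthetic-data generators and their calibration

The generators are structural: they draw the component streams (RI A/E,
within-process A/E, innovations) and combine them, never sampling from the
implied joint covariance, so the implied-moment builders remain an
independent oracle for them.  Fixed seeds give bit-identical panels.

Default generating values reproduce the reference estimates the recovery
suite targets: RI variance shares 53/58/64% (personality) and 39/38/45%
(psychopathology) across waves, A shares of RI variance 70% and 83%, RI
genetic correlation −0.55, composite heritabilities 0.57/0.63 with
$r_A = -0.513$, $r_E = -0.374$, and the reference loading vectors with
uniqueness $1-\lambda^2$.  Wave-3 total variance is normalized to 1 per
trait; innovation covariances are solved (`solve_innovations()`) so the
within-person variances hit the wave-specific targets exactly.

Quantities no reference value pins down were chosen once, on plausibility,
and are not tuned: within-process cross-trait correlation −0.30 (yields
same-wave phenotypic correlations near −0.4); RI E-correlation −0.30;
within-process A share 0.35 (yields univariate heritabilities near
0.50–0.55, the reported band); autoregressive paths 0.35 (personality) and
0.40 (psychopathology); one non-zero cross-lagged path (personality wave 2 →
psychopathology wave 3) at standardized 0.10 by default; sex mean effects
+0.2 / −0.3; wave dropout probabilities (0, 0.24, 0.37) mirroring reported
wave participation, plus 1% cell MCAR.  MZ co-twins share a sex; DZ sexes
are independent, so about half the DZ pairs are opposite-sex.

What the generators do *not* emulate — and therefore what passing recovery
tests cannot show about real data: non-normal and bounded scale
distributions, floor effects in symptom scales, missingness related to the
phenotype (only MCAR/wave dropout is generated), sibling interaction or
rater effects, assortative mating, age heterogeneity within waves, and any
C variance in the cross-lagged process.

## 6. Recovery behavior and known limitations

Fitting the RI-CLPM to data simulated at the defaults recovers all
parameters without visible bias at 3,000 pairs (the acceptance suite
asserts the reference tolerances; e.g. the RI genetic correlation is
recovered within ±0.07).  Two caveats the package documents rather than
hides:

* **Factor-score attenuation.**  Running the *full* chain — indicators,
  imputation, factor scores, then the RI-CLPM on the scores — attenuates
  RI variance shares relative to the latent generating values, because
  occasion-specific factor-score error inflates apparent within-person
  variance.  `recovery_report()` is therefore a diagnostic table; latent
  parameter recovery is assessed by fitting at the factor level, which is
  also how the acceptance targets are defined.
* **Squared standardized cross-lags are noisy.**  At 1,500 pairs the
  standardized cross-lag estimate has Monte-Carlo sd ≈ 0.035 around a true
  0.10, so the "percent of within-person variance explained" (its square
  ×100) ranges over roughly 0.3–2.5 across seeds; single-replicate values
  should be read accordingly, and the calibration tests use medians over
  replicates.

Monte-Carlo oracle checks compare every covariance entry of the implied
moments with simulation at $n = 10^6$ pairs.  With ~312 entries compared,
a per-entry 3-SE bound would fail by chance for a correct builder about
half the time; the tests therefore use the Šidák-equivalent family-wise
threshold (per-entry ≈ 4.3 SE, chosen so the whole-matrix false-alarm rate
equals that of a single 3-SE comparison).  Spot checks of single quantities
keep plain 3-SE bounds.

Problem sizes used by the test suite (package choices): recovery fits at
3,000 pairs; cross-lag type-I calibration from 100 replicate datasets × 4
generating-zero paths at 500 pairs; fit-index behavior over 100 replicates
at 3,000 pairs; moment oracles at $10^6$ pairs in chunks.  The full suite
runs in a few minutes on one CPU; a single 3,000-pair RI-CLPM fit takes
under a second thanks to the sufficient-statistic likelihood.

Out of scope by design: sex-limitation models beyond sex-specific means,
dominance (D) components, ordinal-threshold liability models, more than
three waves or two traits in the RI-CLPM, bifactor/hierarchical measurement
alternatives, and non-ignorable missingness.
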