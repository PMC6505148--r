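---
title: "Bayesian multi-trait, multi-environment genomic prediction: models and methods"
author: "BayesMTGP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian multi-trait, multi-environment genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BayesMTGP)
```

## The problem

Genomic selection trains a statistical model on lines that are both
genotyped and phenotyped and predicts the performance of candidates that
have only been genotyped. Breeding trials almost always measure several
traits on each line, often in several environments, and the traits and
environments are genetically correlated. Exploiting those correlations is
where multivariate models earn their keep: a trait that is cheap to measure
precisely (say plant height) can sharpen the prediction of a correlated,
noisier trait (grain yield), and a line tested in some environments can be
predicted in the environments where it was never grown.

BayesMTGP implements three model families for this setting:

* a **multi-trait model** for a single environment (`fitMultiTrait`),
* a **multi-trait multi-environment model** with a genotype x environment x
  trait interaction (`fitMultiTraitME`),
* **multi-output regressor stacking** (`fitStacking`, `fitStackingEnv`), a
  cheap two-stage alternative built from univariate fits.

## Models

### Genomic relationship and whitening

Marker dosages W (J lines x p markers, codes 0/1/2) give the genomic
relationship matrix

G = W W' / p

(`grmVanRaden`; no internal centering — the formula is applied to W exactly
as supplied). G enters the models through its Cholesky factor: with
G = L L' (`safeCholesky`), the line design Z_G is replaced by Z1 = Z_G L and
the correlated line effects u ~ N(0, G sigma^2) by whitened effects
b1 ~ N(0, I sigma^2). The same trick applied to the block covariance
I_I (x) G yields the whitened interaction design Z2 (`buildDesign`). For
rank-deficient G (common when J > p) `safeCholesky` clips eigenvalues below
1e-10 times the largest eigenvalue up to that threshold before factorizing —
a deterministic choice in preference to random jitter; the factor then
reproduces the clipped matrix to about 1e-6 relative error.

### The matrix-variate model

For n records on L traits,

Y = X beta + Z1 b1 + Z2 b2 + E,

with (on the whitened scale)

* b1 ~ MN(0, I_J, SigmaT) — line x trait effects,
* b2 ~ MN(0, SigmaE (x) I_J, SigmaT) — line x environment x trait effects,
* E ~ MN(0, I_n, Re),

where SigmaT (L x L), SigmaE (I x I) and Re (L x L) are unstructured
covariance matrices: trait genetic, environment genetic and trait residual
respectively. X is the environment incidence matrix (one column per
environment, no intercept), so beta is the I x L matrix of
environment-by-trait means. MN(M, U, V) denotes the matrix-variate normal:
vec of the matrix is multivariate normal with covariance V (x) U.
`fitMultiTrait` is the same model without X-structure (one intercept per
trait) and without the b2 term.

**Identifiability note.** Only the product SigmaE (x) SigmaT enters the
prior of b2, so the overall scale split between SigmaE and SigmaT is not
separately identified; correlations and variance ratios are. We impose no
normalisation and recommend interpreting `envCov`/`traitCov` on the
correlation scale (`covToCor`). Recovery tests therefore score
correlations, not raw scales.

### Gibbs sampler

All full conditionals are conjugate:

1. beta: matrix-normal (flat prior by default; a proper conjugate
   matrix-normal prior MN(0, tau^2 I, Re) is available via
   `priors$betaVar`, used by the joint-distribution validation tests);
2. b1, b2: the full conditionals do not factor as matrix normals, because
   the likelihood couples traits through Re while the prior couples them
   through SigmaT. The sampler computes the simultaneous diagonaliser M of
   (SigmaT, Re) — M' Re M = I, M' SigmaT M = diag(d) — and transforms the
   trait axis; the transformed trait columns are then conditionally
   independent ridge-type regressions that are sampled exactly, sweeping
   coefficient rows in blocks of `blockSize` (default 50) per the usual
   blocked Gibbs scheme;
3. SigmaT: inverse-Wishart with df nuT + J + IJ, scale
   ST + b1'b1 + b2'(SigmaE^-1 (x) I)b2 — it pools both effect matrices;
4. SigmaE: inverse-Wishart with df nuE + J L and scale SE + T, where
   T[i,k] = tr(B_i SigmaT^-1 B_k') and B_i is the i-th environment block of
   b2 (derived from the matrix-normal prior of the environment-blocked
   layout of b2);
5. Re: inverse-Wishart with df nuRes + n on the residual cross-product;
6. missing or masked Y cells are refreshed from their conditional normal
   given the observed traits of the same record (data augmentation) — this
   doubles as the prediction mechanism for cross-validation.

Posterior summaries (means and SDs) use retained draws only (post burn-in,
thinned). `yHat` accumulates the linear predictor, with masked cells
replaced by their conditional means given the observed traits of the same
record, which reduces Monte-Carlo noise relative to accumulating the
augmented draws while retaining the cross-trait correction.

### Priors and defaults

The covariance priors are proper and weakly informative:
nuT = nuRes = L + 2, nuE = I + 2, identity scale matrices. These guarantee
valid inverse-Wishart updates at toy sizes; all are overridable through the
`priors` argument. The chain defaults mirror common practice for these
models: `thin = 2`, `blockSize = 50` (allowed range 50 to 999); `nIter` and
`burnIn` have no universal default and must be chosen per analysis —
parameter estimates stabilise quickly, so demonstration-sized chains
(1250/500) are usable for cross-validated accuracy while longer chains
(15000/10000 or 30000/20000) are appropriate for reported estimates.

### The univariate engine

`fitUnivariate` implements the single-trait Gibbs sampler used by GBLUP-type
fits and by both stages of stacking: an intercept, any number of predictor
components, and per-component priors. `BRR` components (Bayesian ridge)
carry iid normal effects with a scaled-inverse-chi-square variance;
`BayesB` components carry a per-effect spike-and-slab (point mass at zero
with probability pi, scaled-t slab via a per-effect
scaled-inverse-chi-square variance, Beta prior on pi). The variance-scale
hyperparameters are set so the prior mode equals half the sample variance of
the observed response, split equally across components, with 5 prior df —
a standard weakly informative default for whole-genome regression; the
exact prior constants of other implementations are not reproduced here, so
posterior summaries are comparable but not identical to them. `BayesA`,
`BayesC` and `BL` are recognised labels that raise a clear
"not implemented" error rather than silently falling back.

### Regressor stacking

`fitStacking` runs, per cross-validation partition: (1) a univariate fit
per trait with the caller's full component list (testing rows masked),
giving predictions at all records; (2) column standardisation of the L
prediction vectors (sample SD, n - 1 denominator, statistics over all n
records of the prediction vector); (3) a per-trait meta-model of the
response on the L scaled predictions plus an intercept (`covModel`, BRR by
default, BayesB available), with the same testing rows masked. Stage 1 is
refitted inside every partition: the alternative (one global stage-1 fit)
would leak testing information into the stage-2 covariates. The stage-2
covariate set is exactly the L scaled predictions — the meta-model's point
is to correct each trait's prediction with the others'. `fitStackingEnv`
masks whole environments instead of random cells and reports accuracy per
held-out environment; with one testing set, no standard errors are
reported.

## Cross-validation designs

* `cvRandomPartition(table, nPartitions, pTesting, seed)` draws, per
  partition, m = round(pTesting * N) lines (half-up rounding; the rounding
  rule is ours, the size formula uses total records N), with replacement
  exactly when fewer distinct lines than m exist; each drawn line
  contributes one of its environments uniformly at random. Duplicate cells
  from with-replacement draws collapse into a set, so a testing set can be
  smaller than m; across partitions a cell may recur.
* `cvKFold(table, k, seed)` deals each line's records onto consecutive
  positions of a cyclically repeated shuffled fold order, which makes folds
  exhaustive and disjoint with sizes differing by at most one, and spreads
  each line's records over distinct folds whenever it has at most k
  records — the CV2 design: lines tested in some environments, trained in
  the others.

Both are pure functions of (table, parameters, seed). Record order is the
canonical one (environment then line, byte-wise collation — results do not
depend on the session locale); `canonicalizePheno` is applied internally
wherever ordering matters, since a silent mismatch between phenotype order
and design matrices is the classic source of wrong estimates in this
workflow.

## Accuracy metrics

Per (environment, trait, partition) over testing cells:

* Pearson correlation (`pearsonCor`); degenerate testing sets (zero
  variance, fewer than two pairs) yield NaN rather than an error;
* MAAPE (`maape`): mean of atan(|(obs - pred)/obs|), bounded by pi/2 and
  usable when observations contain zeros; obs = 0 with a different
  prediction contributes atan(Inf) = pi/2, an exact match contributes 0.

`summarizeMetrics` averages over partitions and reports
SE = sd / sqrt(#partitions); with one partition the SE is NaN (no standard
error exists for a single testing set). Pearson values are averaged
directly (not through Fisher's z).

## The synthetic-data generator

`simulateMarkers` draws dosages binomial(2, f) with per-marker frequencies
uniform on a range; `simulateTraits` draws b1 ~ MN(0, G, SigmaT),
b2 ~ MN(0, SigmaE (x) G, SigmaT), E ~ MN(0, I, Re) and assembles Y over the
complete J x I layout, returning the realized effects for oracle
comparisons. Two presets fix the toy geometries used throughout the
documentation: `mada_like` (30 lines, 6 centred wheat-like traits, one
environment) and `maize_like` (30 lines, 3 maize-like traits — yield around
6 t/ha, anthesis-silking interval around 2 d, plant height around 240 cm —
in 3 environments with environment correlations 0.8 and heritabilities
around one half).

What the generator emulates: the record layout, trait scales, covariance
structure and missingness mechanics of small breeding trials. What it does
not: linkage disequilibrium and family structure in the markers (lines are
simulated unrelated), non-Gaussian traits, spatial field trends, and
genotype-by-environment structure beyond the separable
SigmaE (x) G covariance. Passing recovery tests on these fixtures therefore
validates the estimation machinery, not the adequacy of the model for any
particular real trial.

## Validation strategy and problem sizes

Published accuracy tables for these models depend on the original bundled
data sets and RNG streams, so they are not desk-reproducible; the package
instead validates itself with properties:

* **Joint-distribution ("getting it right") tests**: forward draws from
  prior + likelihood vs a successive-conditional chain that alternates the
  Gibbs scan with redrawing the data; first two moments of tested
  parameters must agree (|z| < 4), run at tiny sizes (n of 6 to 8, two
  traits, two environments) with proper priors whose dfs are large enough
  (12 to 13) that the compared fourth moments exist. This is the primary
  correctness gate for the environment-covariance full conditional.
* **Oracle equivalence**: with all covariance matrices fixed at truth, the
  Gibbs posterior means of (beta, b1, b2) must match a dense GLS solve of
  the vectorized system (J = 4, I = 2, L = 2) within Monte-Carlo error.
* **Parameter recovery**: the full model at J = 100 lines, 3 environments,
  3 traits, 4000 iterations must recover trait genetic correlations within
  0.25 absolute in at least 8 of 10 seeds. The simulated truth uses
  strongly correlated (0.7 / -0.5 / -0.4), high-heritability traits with a
  mild interaction: a power analysis shows that with weak correlations or
  low heritability the single-realization sampling noise of the effects
  alone (roughly (1 - r^2)/sqrt(J)) plus posterior shrinkage makes the
  estimand unrecoverable at this size, so a recovery test there would
  measure the generator, not the sampler. For the same reason the
  single-environment recovery test uses a replicated design (4 records per
  line): without replication or relatedness, the genetic and residual
  covariances separate only weakly and genetic correlations attenuate
  towards zero regardless of sampler correctness.
* **Stacking behaviour**: with one precise and one noisy trait, mean
  testing accuracy must be higher when the simulated genetic correlation
  is 0.9 than when it is 0.0 — the meta-model has something to borrow only
  in the first case.

Monte-Carlo standard errors for chain means are computed by batch means;
"agreement" in the oracle test means all |z| < 4 with RMS z < 2 across
entries, which is the appropriate frozen-test version of agreement within
Monte-Carlo error for dozens of entries.

## Numerical choices, degenerate inputs, limitations

* Eigenvalue clipping threshold 1e-10 x largest eigenvalue (Cholesky);
  trait-transform prior variances floored at 1e-12 of their maximum.
* The zero matrix factors to the zero matrix; covariance matrices with
  non-positive diagonals are rejected with the offending trait named.
* Marker QC order is fixed: missingness filter, then imputation by
  binomial(2, observed frequency) draws, then the MAF filter computed
  after imputation (documented choice; the alternative — MAF before
  imputation — differs only for markers near the threshold).
* Half-up rounding for testing-set sizes.
* Undefined summary values propagate as NaN and render as "NaN" in CSV.
* The identical-seed contract gives bitwise identical results for
  identical inputs; permutation equivariance (relabelling traits or
  environments) holds in distribution, not bitwise, because the RNG stream
  is consumed in a different order.
* Non-Gaussian traits, heterogeneous residual covariances across
  environments, and structured (factor-analytic, autoregressive)
  environment covariances are out of scope.
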