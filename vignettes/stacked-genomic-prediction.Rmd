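---
title: "Two-stage Bayesian stacking for multi-trait multi-environment genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage Bayesian stacking for multi-trait multi-environment genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The prediction problem

Breeding programs evaluate J candidate lines in I environments for L
correlated traits, and routinely face *incomplete* trials: a line has
phenotypic records in some environments but must be predicted in others.
Genomic selection addresses this by borrowing information across lines
through a marker-derived relationship kernel; multi-trait methods
additionally borrow across traits. Fully multivariate Bayesian models do
this well but are expensive: their Gibbs samplers scale poorly with L and
I. This package implements a cheaper two-stage alternative — multi-output
regressor stacking in a Bayesian form — together with the univariate
baseline, the cross-validation scheme used for incomplete trials, and a
simulator with known truth so that every claim can be checked end to end.

## Stage one: univariate GBLUP with genotype-by-environment interaction

For each trait, `gblup_ge()` fits

$$y_{ij} = E_i + g_j + gE_{ij} + e_{ij},$$

where $E_i$ is the fixed effect of environment $i$ (Gaussian prior with
variance $10^{10}$, i.e. effectively flat but proper), $g = (g_1, \dots,
g_J)^\top \sim N(0, \sigma_1^2 G)$ is the vector of genomic line effects,
$gE \sim N(0, \sigma_2^2\, I_I \otimes G)$ the genotype-by-environment
deviations, and $e_{ij} \sim N(0, \sigma^2)$. The kernel is the genomic
relationship matrix

$$G = \frac{WW^\top}{p},$$

computed by `compute_grm()` from the $J \times p$ dosage matrix after
quality control (`filter_markers()`) and column-mean imputation
(`impute_markers()`). Columns of $W$ are centered at their means by
default: an uncentered 0/1/2 coding makes $G$ depend on which allele is
labelled as the reference, while centering gives the standard
construction (label-swap invariance is asserted in the tests). A
`center = FALSE` flag exposes the raw cross-product. The denominator is
$p$, the marker count, not $2\sum p_k(1-p_k)$; variance components are
therefore expressed in units of this kernel, which is also the kernel the
simulator uses, so simulation truth and fitted components are directly
comparable.

### Priors and their parameterization

Variance components carry scaled inverse-$\chi^2$ priors in the
$S/\chi^2_v$ parameterization: mode $S/(v+2)$, mean $S/(v-2)$. Scales are
elicited as

$$S = \widehat{\mathrm{Var}}(y_{\mathrm{train}}) \times R^2 \times (v+2),$$

so the prior *mode* of each component is the share $R^2$ of the
phenotypic variance assigned to it. Defaults, all with $v = 5$: $R^2 =
0.5$ for the genomic component and $0.25$ for the residual. The
interaction component has no stated convention in the stacking
literature we follow; we give it $R^2 = 0.25$ so that the three prior
modes partition the phenotypic variance as $0.5 + 0.25 + 0.25$. All of
this is per-trait and recomputed from the training records of each fit;
`gblup_ge()` stores the derived scales in `fit$prior` for audit.

### The Gibbs sampler

All full conditionals are conjugate; no Metropolis steps are used. Fixed
effects have a diagonal conditional precision (incidence design) and are
drawn as independent scalars. The two kernel-structured blocks are drawn
*jointly* from their exact Gaussian full conditionals, which matters for
mixing when lines appear in several environments.

A naive joint draw would factorize a $J \times J$ conditional precision
every iteration. Instead, each block's likelihood cross-product is
constant across iterations (only the two variances multiplying it
change), so we precompute once per fit, per block, the eigendecomposition
of the *whitened* cross-product $D^{1/2} U^\top Z^\top Z U D^{1/2}$,
where $G = U D U^\top$ (rank-truncated, see below). Every iteration then
reduces to two $r \times r$ matrix–vector products — about 2.5 ms per
iteration at $J = 300$, $I = 3$ — and the draw is still *exact*, for any
training mask. (A sketch often seen for this model samples
coordinate-wise in the eigenbasis of $G$, but the conditional is diagonal
there only when every line has the same number of records, which a
random cross-validation mask destroys.)

Numerical choices:

* `kernel_eigen()` drops eigenvalues below $10^{-8} \lambda_{\max}$;
  a centered marker kernel always has the null vector $\mathbf{1}$, and
  effects are sampled in the surviving rank-$r$ basis, which is also how
  the prior metric $G^{-}$ in the variance updates is regularized
  (quadratic form $\sum_k a_k^2 / d_k$, degrees of freedom $r$ and $Ir$).
  Eigenvalues below $-10^{-8}\lambda_{\max}$ are an error, not repaired.
* Lines with no training records (whole-line masking) need no special
  path: their coordinates in the eigenbasis are drawn through the kernel
  correlation with trained lines.
* Chains default to 10 000 iterations, 5 000 burn-in, thinning 5
  (`mcmc_control()`); a constant response degenerates
  $\widehat{\mathrm{Var}}(y)$ to $10^{-8}$ rather than zero so the priors
  stay proper.
* Predictions are posterior means of the linear predictor
  $E_i + g_j + gE_{ij}$, which, being linear, are sums of the stored
  posterior means — for training and testing cells alike.

`fix_variances` freezes any subset of the three components, which turns
the sampler into a draw from a fixed Gaussian posterior; the test suite
uses this to compare posterior means against direct mixed-model-equation
solves at tolerance 0.02, and against the textbook ridge shrinkage
$(y-\bar y)/(1+\sigma^2/\sigma_1^2)$ in the identity-kernel,
one-environment case.

## Stage two: ridge stacking of scaled predictions

`bmors()` first fits the L univariate models on the *training* cells and
predicts all $N = J \times I$ cells. The L prediction vectors are
standardized (`scale_predictions()`: mean 0, sample SD 1, $n-1$
denominator) and become the covariates of L per-trait meta-models

$$y_{ij} = \beta_0 + \beta_1 \hat Z_{1ij} + \dots + \beta_L \hat Z_{Lij} + e_{ij},$$

fitted by `bayes_ridge()` with $\beta_k \sim N(0, \sigma_\beta^2)$,
$\sigma_\beta^2$ and the residual variance again scaled
inverse-$\chi^2$ with $v=5$ and $R^2 = 0.5 / 0.25$. Decisions worth
recording:

* **Scaling statistics** are computed over *all* N cells' stage-one
  predictions. Test-cell predictions require no test labels, so this
  leaks nothing, and it means a single, well-defined transform maps any
  cell into the meta-feature space. The alternative reading of the
  scaling subscripts as per-cell quantities would standardize each value
  by its own mean and SD and make the features identically zero; we read
  them as per-trait scalars.
* **An intercept** (prior $N(0, 10^{10})$) is included even though the
  stacked equation is usually written without one: the covariates are
  centered and the response is not, so without it the meta-model is
  mis-located.
* **One pooled regression per trait** across environments (the index set
  of the stacked equation runs over all cells), not per-environment
  meta-models; per-environment accuracy summaries are still available
  downstream (`by_env`).
* **Coefficients are unconstrained** — non-negativity restrictions were
  evaluated in the literature this method comes from and degraded
  accuracy — and the original marker features are *not* appended to
  stage two, for the same reason.
* **Training covariates are in-sample fitted values** by default, which
  is the cheap variant this method is valued for; classic stacking's
  out-of-fold covariates are available behind `inner_cv = TRUE`.

With a single trait, stage two is an affine map of the one covariate, so
the stack reproduces the univariate ranking exactly (|Pearson r| = 1);
this collapse is asserted in the tests and is a useful sanity check that
no information is created out of nothing.

## Cross-validation and metrics

`make_partitions()` mimics incomplete trials: $m = \mathrm{round}(p_{\mathrm{test}} N)$
lines are drawn — with replacement if $J < m$, without otherwise — and
one environment is picked uniformly for each drawn line; the resulting
cells (duplicates collapsed, so $|TST|$ can fall slightly below $m$ under
replacement) form the testing set. Default $p_{\mathrm{test}}$ settings
of 0.2 and 0.4 correspond to 80/20 and 60/40 designs; rounding is R's
`round` (half to even); every model is evaluated on byte-identical
partitions.

Accuracy is summarized per trait (pooled across environments, matching
the one-row-per-trait reporting convention; per-environment rows on
request) by the across-partition mean and sample SD of:

* **APC** — Pearson correlation between observed and predicted testing
  values; reported as missing (not 0) when either vector has no spread,
  so constant predictors are not silently rewarded.
* **MAAPE** — `mean(atan(|(y - ŷ)/y|))`, in radians, bounded by
  $\pi/2$; a zero observation contributes $\pi/2$ unless the prediction
  is also zero (then 0). It is finite where relative errors are not.

## The simulator and what passing tests mean

`simulate_phenotypes()` draws from the matrix-variate model
$Y = X\beta + Z_1 b_1 + Z_2 b_2 + E$ with $b_1 \sim MN(0, G, \Sigma_t)$,
$b_2 \sim MN(0, \sigma^2_{gE}\, \Sigma_E \otimes G, \Sigma_t)$ and iid
residual rows $N(0, R_e)$ — the natural multi-trait generative structure,
used here *only* to generate data (its fully multivariate fitter is a
different model family and out of scope). With $L = 1$, $\Sigma_E = I$,
it reduces exactly to the stage-one model, which is what the
variance-recovery checks exploit. Factorizations add a relative jitter of
$10^{-8}\lambda_{\max}$ before Cholesky.

`simulate_scenario()` fixes the reference conditions used throughout the
checks: $J = 300$ lines, $I = 3$ environments, $L = 3$ traits, $p = 1000$
markers with allele frequencies uniform on $[0.05, 0.5]$, unit genomic
variance, interaction variance 0.5, residual variance 0.5, a common
genetic correlation between traits (0.5 unless varied), and environment
means near 10 (spread ±1) so MAAPE is on the familiar small-relative-
error scale of real traits. These sizes complete a full 10-partition
two-model cross-validation in a few minutes on one CPU; the oracle checks
use smaller fixtures (J = 8–60) with long chains (20 000 retained draws)
where exactness at tight tolerance is the point, and 1 500–3 000
iteration chains where only posterior-mean predictions are needed.

What the simulator does *not* emulate — and hence what passing tests do
not establish about real data: linkage disequilibrium and marker
ascertainment, population structure and kinship beyond the simulated
kernel, selection, spatial field trends, heterogeneous error variances
across environments, and phenotypes that are adjusted means (BLUEs) from
an upstream field-design model, which this package treats as given.

## Known limitations

* Stage one is GBLUP only; the seam for other first-stage learners
  exists (any N×L prediction matrix can be passed through
  `scale_predictions()` + `bayes_ridge()`) but no alternative ships.
* The stack does not estimate genetic or residual covariances between
  traits — the price of the two-stage shortcut; its coefficients are
  predictive weights, not genetic parameters.
* Leave-one-environment-out evaluation and k-fold or stratified CV are
  not implemented; the partition scheme is the incomplete-trial design
  described above.
* On simulated data the stack tracks the univariate baseline closely
  (within the 0.05 APC band asserted in the tests) rather than beating
  it; its practical appeal is cost relative to fully multivariate
  models, not accuracy gains.
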