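---
title: "Spatial REML models for clonal spectral trials: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial REML models for clonal spectral trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonespec)
```

## The scientific problem

In a clonal field trial (a "clone bank"), each genotype is vegetatively
propagated into several ramets, so the total genetic variance of any trait is
directly estimable from the variance between clones. `clonespec` treats shoot
hyperspectral reflectance (350--2,500 nm bidirectional reflectance factors),
vegetation indices derived from it, photosynthetic pigment content and growth
traits as quantitative-genetic characters in such a trial, and answers three
questions: how heritable is each character, how strongly are characters
genetically correlated, and where along the spectrum do groups (ecotypes,
sampling dates) differ.

Field trials are spatially structured: fertility and microsite gradients
induce correlations between neighbouring trees that inflate apparent genetic
variance if ignored. The models here therefore combine a smooth fixed trend
with a stationary autoregressive error field.

## The univariate model

For a trait $y$ observed on $n$ trees at row/column positions $(r_i, c_i)$:

$$ y = \mathbf{1}\mu + X_r\beta_x + X_c\beta_y + Zc + e $$

* $X_r$, $X_c$ are second-order **orthogonal polynomial** bases in the row
  and column index (unit-norm, mutually orthogonal; `stats::poly`). Using
  orthogonal rather than raw polynomials keeps the design well conditioned
  and makes the trend coefficients interpretable independently.
* $c \sim N(0, \sigma^2_c I)$ is the clone effect; with clonal replication
  $\sigma^2_c$ is the total (broad-sense) genetic variance.
* $e \sim N(0, R)$ with either $R = \sigma^2 I$ (iid) or the separable
  spatial structure
  $R = \sigma^2\,[\mathrm{AR1}(\rho_{col}) \otimes \mathrm{AR1}(\rho_{row})]$.
  For the observed (possibly incomplete) set of trees the covariance between
  trees at $(r_1,c_1)$ and $(r_2,c_2)$ is
  $\sigma^2 \rho_{row}^{|r_1-r_2|}\rho_{col}^{|c_1-c_2|}$ — the submatrix of
  the full Kronecker matrix, built directly from coordinates so holey grids
  need no imputation. Lags are absolute index differences (1-based integer
  grid), the standard convention for row/column trials.

Estimation is REML: the reported log-likelihood is the Gaussian log-density
of error contrasts $K'y$ ($K$ an orthonormal basis of the orthogonal
complement of the fixed-effect design), a convention that is invariant to the
choice of $K$ and reproducible by direct dense-matrix evaluation — the test
suite checks exactly that equivalence at $10^{-6}$.

### Optimization

Fixed effects and the residual scale are profiled out analytically, leaving
at most three free parameters: $\gamma = \sigma^2_c/\sigma^2$ and the two
autocorrelations. The search evaluates the profiled likelihood on a small
start grid ($\gamma \in \{0.1, 1, 3\}$, $\rho \in \{0, \pm 0.5\}$), refines
the best start by Nelder-Mead on transformed coordinates
($\log\gamma$, $\mathrm{atanh}(\rho/0.99)$; convergence tolerance $10^{-10}$
relative, with one polishing restart), and finally compares the interior
optimum against an explicit fit on the $\sigma^2_c = 0$ boundary, so null
clone variances land exactly on the boundary rather than at a tiny positive
value. $|\rho| \le 0.99$ keeps the spatial correlation well conditioned.

The covariance matrix of the variance parameters is the negative inverse of a
central-difference Hessian of the restricted log-likelihood at the optimum
(step $10^{-4}\max(|\theta_i|, 0.01)$). REML software based on average
information returns the same matrix at convergence.

### Heritability and model comparison

Broad-sense heritability is $H^2 = \sigma^2_c/(\sigma^2_c + \sigma^2)$, with
a delta-method standard error using the gradient
$(\sigma^2, -\sigma^2_c)/(\sigma^2_c+\sigma^2)^2$. The test of
$\sigma^2_c = 0$ is a REML likelihood-ratio test; because the null pins a
variance at its boundary the reference distribution is the equal mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ (the test suite verifies a 5%
rejection rate within $\pm 2$ points over 1,000 null simulations).
Autocorrelation parameters are interior, so their LRTs use a plain
$\chi^2$. Wald F-tests of fixed terms use containment-style denominator
degrees of freedom ($n - \mathrm{rank}(X)$), a deliberate simplification
(labelled in the output); Kenward-Roger adjustments are out of scope.

## The bivariate model and genetic correlations

Genetic correlations come from stacking two traits:

$$ y = X_1 t + X_1 t{:}\beta_x + X_2 t{:}\beta_y + Z_1 tc + Z_2 u + e $$

with a trait main effect, trait-nested polynomial trends, a clone effect
nested within trait ($tc \sim N(0, G_c \otimes I_c)$, $G_c$ the unstructured
2x2 clonal covariance), a shared tree effect
$u \sim N(0, \sigma^2_u I)$ carrying the cross-trait correlation of
observations on the same tree, and trait-block-diagonal residuals (iid or
AR1xAR1 per trait, re-estimated inside the bivariate fit). The genetic
correlation is $r_g = G_{12}/\sqrt{G_{11}G_{22}}$.

Design choices:

* $G_c$ is parameterized by its Cholesky factor during optimization, which
  enforces positive semi-definiteness without constraints; $r_g$ is derived
  after back-transformation.
* Estimates with $|r_g| > 0.999$ are reported as $\pm 0.999$ with flag
  `"B"` and no standard error — at the boundary the Hessian is singular and
  a delta-method SE would be meaningless. This mirrors how clonal-trial
  studies print boundary correlations.
* Significance of $r_g$ is a 1-df LRT against the fit with the $G_c$
  off-diagonal fixed at zero (an interior null).
* $\sigma^2_u$ is shared across traits — the minimal structure that induces
  within-tree cross-trait correlation. A consequence is that the model is
  not invariant to rescaling one trait alone, so the fit rescales both
  traits by a single common factor for numerical conditioning (exactly
  model-preserving) and relies on moment-based starting values, in log
  coordinates, to absorb scale differences between traits.
* The two traits are ordered canonically (by name) inside the fit, making
  results bit-identical under swapping the input order.

## Spectra, indices, pigments

Repeated scans of one sample are aggregated by the per-wavelength **median**.
The vegetation-index registry ships two dialects: `"paper"` (default) holds
the formulas exactly as printed in the index table of the study this design
follows — CRI2 $= R_{760}/R_{700} - 1$, DWSI4 $= R_{550}/R_{680}$,
GI $= R_{554}/R_{677}$, SR3 $= R_{750}/R_{550}$, SR4 $= R_{700}/R_{670}$,
SR5 $= R_{675}/R_{700}$, TCARI2 $= 3[(R_{750}-R_{705}) -
0.2(R_{750}-R_{550})(R_{750}/R_{705})]$ — while `"canonical"` swaps in the
literature definition where the two differ (CRI2 as
$1/R_{510} - 1/R_{700}$). The printed-table alignment of names to formulas
is typographically ambiguous in places, which is exactly why the dialect is
explicit rather than silently resolved. Wavelength lookup is exact on the
integer grid with a 1 nm nearest-neighbour fallback (safe on a 1 nm
instrument grid); zero denominators yield flagged `NA`s, not errors.

Pigment contents use the Lichtenthaler 80%-acetone equations by default
(chlorophyll a: $12.25 A_{663} - 2.79 A_{646}$ ug/ml, etc.), converted to
mg g$^{-1}$ dry mass via the extract volume (default 10 ml) and dry mass
(default 25 mg). The equation set is pluggable (a Wellburn-1994 set is
included) and stamped on every output row because the choice moves results
by a few percent. Negative computed pigments are flagged, never truncated.

## The synthetic trial generator

No raw data ship with this package; every analysis is exercised on a
generator whose ground truth is known:

* **Layout**: clones placed randomly or as clonal rows on an integer grid;
  ecotype labels (`low`, `medium`, `high`) are clone-level attributes.
* **Genetic values**: one MVN draw per clone with trait covariance $G$.
* **Spatial field**: second-order polynomial trend plus AR1xAR1 noise —
  exactly the structures the models estimate.
* **Traits**: mean + genetic value + spatial field (+ optional clone-level
  ecotype shifts; ecotype enters only as a mean shift because the analysis
  models treat ecotype by post-hoc comparison, not as a model term).
* **Spectra**: a fixed vegetation-like baseline (low visible reflectance
  with a green bump, logistic red-edge rise at 680--750 nm, NIR plateau,
  smooth SWIR decay) minus Gaussian absorption features: 680/550 nm depths
  increase in total chlorophyll, 970/1,200/1,450/1,930 nm depths in a latent
  water variable, and the 760--1,300 nm plateau rises with a latent
  structure variable; iid Gaussian noise, clipped to [0, 1].

Default conditions emulate the mature Norway-spruce clone bank that
motivated the design: 30 clones x 3 ramets on a 10 x 10 grid (about 90
sampled trees), trait means and dispersions per the trial's descriptive
statistics (height 20.6 m, DBH 33 cm, chlorophyll a around 3.1 mg/g),
per-trait $H^2 = 0.4$, a common genetic correlation of 0.5,
$\rho_{row} = \rho_{col} = 0.5$. These defaults were fixed once, from the
descriptive tables, as the generator's study conditions.

What the generator does **not** emulate: radiative transfer (no
PROSPECT-style leaf optics), instrument noise structure, needle-age effects,
or genotype-by-environment interaction. Passing tests therefore demonstrate
that the estimators recover the parameters of this generative model — they
are statements about the statistical machinery, not about any particular
field dataset.

## Scans and reports

Wavelength-wise analyses run the scalar machinery per column: paired t-tests
between sampling dates on matched trees (unmatched trees dropped with a
logged count; zero-variance differences flagged, $p = 1$), Fisher's LSD for
ecotype comparisons (one-way pooled variance, unadjusted p-values — matching
the reporting convention of such trials; no multiple-testing correction is
applied across wavelengths by design), Pearson correlation scans with
$SE = \sqrt{(1-r^2)/(n-2)}$, heritability scans (flagging columns with clone
LRT $p < \alpha$ as "heritable" — the pre-selection rule for which indices
enter genetic-correlation analysis), and genetic-correlation scans.
Per-column failures (constant columns, collapsed clonal variances) are
recorded in the output rather than aborting a scan.

`significant_regions()` compresses a p-value vector into maximal runs of
consecutive grid wavelengths with $p < \alpha$; the intervals are inclusive,
disjoint, and exactly invert to the significant set.

## Numerical choices and degenerate inputs

* Constant responses are rejected before optimization.
* Missing responses are dropped listwise per trait; retained trees keep
  their original coordinates so spatial lags are unaffected.
* Likelihood evaluations that fail Cholesky (indefinite covariance at an
  extreme iterate) return $-\infty$, steering the optimizer back inside.
* Fits are invariant to lag-preserving relabelling of rows and columns.
* Monte-Carlo test sizes (200 replicates for parameter recovery, 1,000 for
  calibration, trials of 90 trees) were chosen to put Monte-Carlo error
  comfortably inside the asserted tolerances.

## Known limitations

* One residual field per trait: no multi-date repeated-measures covariance.
* No Kenward-Roger or Satterthwaite degrees of freedom.
* The bivariate model assumes both clonal variances are positive; traits
  without clonal variance raise an explicit undefined-correlation error
  rather than a spurious estimate.
* Wavelength-level heritability scans fit one model per wavelength (2,151
  fits for a full spectrum); for exploratory use, scan a subset or the
  index table first.
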