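# clonespec

Quantitative genetics of hyperspectral reflectance in clonal field trials.

## What it is for

In a clonal trial ("clone bank") each genotype is replicated as several
grafted ramets, so the total genetic variance of any measured character is
estimable from the between-clone variance. `clonespec` treats shoot
hyperspectral reflectance (350–2,500 nm), vegetation indices, needle pigment
content and growth traits as quantitative-genetic characters in such a trial.
It is aimed at forest geneticists and plant phenotyping researchers who want
to ask: *how heritable is a spectral or growth trait, how strongly are traits
genetically correlated, and where along the spectrum do ecotypes or sampling
dates differ?*

The statistical core is a spatial linear mixed model fitted by REML,

```
y = 1*mu + X_r*beta_x + X_c*beta_y + Z*c + e
c ~ N(0, sigma2_c * I),   e ~ N(0, R)
R = sigma2 * I      or     R = sigma2 * [AR1(rho_col) ⊗ AR1(rho_row)]
```

with second-order orthogonal polynomial trends in the row and column index
and, optionally, a separable first-order autoregressive error field over the
trial grid (observed trees use the corresponding submatrix of the Kronecker
covariance, so incomplete grids need no imputation). From the fit:

* broad-sense heritability `H2 = sigma2_c / (sigma2_c + sigma2)` with a
  delta-method standard error and a boundary-corrected (½χ²₀ + ½χ²₁)
  likelihood-ratio test of `sigma2_c = 0`;
* genetic correlations `r_g = G12 / sqrt(G11 * G22)` from a stacked
  bivariate model with an unstructured 2×2 clonal covariance, a shared
  tree effect, and per-trait residual blocks — boundary estimates
  (|r_g| > 0.999) are clamped and flagged `"B"`.

Around the core: a synthetic clonal-trial generator with known ground truth
(genetic values, spatial surface, trait-linked spectra), a vegetation-index
registry (CRI2, DWSI4, GI, SR3, SR4, SR5, TCARI2 — as printed in the study
tables this design follows, with a canonical-literature dialect switch),
pigment quantification from 80%-acetone extract absorbances, and
wavelength-wise scans (paired t-tests, Fisher's LSD, Pearson correlations,
heritability and genetic-correlation scans) with contiguous
significant-region extraction.

## Worked example

```r
library(clonespec)

# a 10x10 trial: 30 clones x 3 ramets, AR1xAR1 microsites, linked spectra
trial <- simulate_trial(seed = 42)
idx <- compute_indices(trial$spectra)   # paper-dialect index registry

# heritability of the SR3 index under the spatial model
fit <- reml_fit(idx$SR3, trial$layout)
fit
#> Spatial linear mixed model (REML)
#>   residual structure: ar1xar1
#>   sigma2_c = 0.111, sigma2 = 0.2343, rho_row = 0.138, rho_col = 0.459
#>   REML log-likelihood = -63.1528 (n = 90)

red <- reml_fit(idx$SR3, trial$layout, include_clone = FALSE,
                compute_vcov = FALSE)
heritability(fit, reduced = red)
#> H2 = 0.321 (SE 0.107), LRT p = 0.0005949

# genetic correlation between chlorophyll a and the CRI2 index
st <- stack_bivariate(trial$traits$chl_a, idx$CRI2, trial$layout,
                      trait_names = c("chl_a", "CRI2"))
biv <- reml_fit_bivariate(st, structure = "ar1xar1")
genetic_correlation(biv, test = TRUE)
#> r_g(chl_a, CRI2) = 0.920 (SE 0.081), LRT p = 1.512e-06

# pigment content from a reference assay (10 ml extract, 25 mg dry mass)
pigment_content(0.50, 0.20, 0.30)
#>    chl_a chl_b       car coefficient_set  flag
#> 1 2.2268   0.7 0.2850163   lichtenthaler FALSE
```

Reading the output: about a third of the SR3 variation in this simulated
trial is clonal (H² = 0.32, clearly nonzero by the boundary LRT); the CRI2
index is strongly genetically correlated with chlorophyll a (r_g = 0.92),
as expected since the generator links the 680/550 nm absorption depths to
total chlorophyll; the assay converts to 2.227 mg chlorophyll a per gram
needle dry mass.

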