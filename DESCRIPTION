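Package: clonespec
Title: Quantitative Genetics of Hyperspectral Reflectance in Clonal Field Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative-genetic analysis of shoot hyperspectral
    reflectance and growth traits in clonal field trials. Provides a synthetic
    clonal-trial generator with known ground truth (clone genetic values, a
    second-order spatial trend, separable AR1xAR1 microsite noise, and
    trait-linked reflectance spectra), restricted maximum likelihood (REML)
    fitting of spatial linear mixed models with clone variance and AR1xAR1
    residual correlation, broad-sense heritability with delta-method standard
    errors, stacked bivariate models for genetic correlations between traits,
    wavelengths and vegetation indices, vegetation-index and pigment
    quantification, and wavelength-wise comparison and correlation scans with
    contiguous significant-region extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
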