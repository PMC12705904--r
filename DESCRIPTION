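Package: dentinemap
Title: Micro-Mapping of Hypochlorite-Induced Collagen Degradation in Root Dentine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for micro-mapping sodium hypochlorite (NaOCl)
    induced collagen degradation in root dentine from point Raman
    micro-spectroscopy transects and reference-point micro-indentation.
    Provides spectral preprocessing (asymmetric-least-squares baseline
    correction, moving-average smoothing, carbonate-band normalization),
    Amide I/III band feature extraction (peak heights, FWHM, integrated
    areas, doublet contrast, signal-to-noise), a quality-index rating and
    inclusion filter, tooth morphometry arithmetic (maturity index,
    instrumented volume), distance-binned gradient regression with
    covariates, saturating-exponential decay fits with boundary estimation,
    and indentation depth-gradient statistics (binned ANOVA with Bonferroni
    post hoc, near-lumen group comparison, logarithmic trend fits). A
    synthetic-data generator emulates the spectral and mechanical structure
    of the irrigation model so every stage is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
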