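# dentinemap

Micro-mapping of sodium hypochlorite (NaOCl) induced collagen degradation
in root dentine, from point Raman micro-spectroscopy transects and
reference-point micro-indentation.

NaOCl, the standard root-canal irrigant, chemically degrades the type-I
collagen matrix of dentine. This package implements, for researchers in
dental biomaterials and vibrational spectroscopy of mineralized tissue,
the complete analysis chain for mapping how far that damage reaches from
the canal lumen toward the cemento-dentinal junction (CDJ):

* **Preprocessing** — asymmetric-least-squares baseline correction
  (Whittaker smoother, band windows zero-weighted), 8-point moving-average
  smoothing, normalization to the carbonate band height
  (1072 cm⁻¹, mineral reference), zero offset.
* **Band descriptors** — peak heights and positions, FWHM, chord-corrected
  integrated areas of the Amide I (1615–1719 cm⁻¹) and Amide III
  (1215–1302 cm⁻¹) bands, Amide III doublet contrast, and SNR
  (peak height over peak-to-peak quiet-window noise, with the printed
  truncate-to-one-decimal convention).
* **Quality filter** — three-region rating against the carbonate height,
  overall general quality, and the quality index
  QI = (r₁ + r₂ + r₃) × general; only spectra with QI ≤ 6 enter the
  area analysis. Fluorescence-masked spectra score QI 27.
* **Morphometry** — maturity index MI = mean(RT)/mean(CW) with floor
  grouping, instrumented canal volume by Archimedes' principle, extent of
  instrumentation.
* **Gradient models** — distance-binned OLS of band area on distance
  (per 100 µm, half-open 100 µm bins, instrumentation covariate, maturity
  strata), a saturating-exponential decay fit
  y(d) = y∞ − (y∞ − y₀)·exp(−d/λ) of the Amide I height with the boundary
  of effect at 95 % recovery (λ·ln 20), and the quality-vs-distance trend.
* **Indentation** — Total Indentation Distance binned by distance, one-way
  ANOVA with Bonferroni post hoc, Welch comparison of test vs control
  within 200 µm of the lumen, and the logarithmic trend
  depth = a − b·ln(d + c).
* **Synthetic data** — a generator that emulates the study's spectra
  (four collagen/mineral bands, doublet flattening and Amide attenuation
  within λ = 250 µm of the lumen, fluorescence-masked inter-tubular
  sites, noise ∝ 1/√acquisition time) and indentation records
  (logarithmic depth trend, deeper for NaOCl-treated teeth), so the whole
  chain is testable without instrument data.

## Worked example

```r
library(dentinemap)

model <- degradation_model()          # lambda = 250 um, floors 0.35
tr <- generate_transect("T1", "A", n_points = 18, spacing_um = 50,
                        model = model, seed = 42)
feats <- analyze_spectra(tr$spectra, tr$manifest)
table(feats$accepted)
#> TRUE
#>   18

fit_decay(feats$distance_um, feats$h_amide1)
#> <decay_fit> y(d) = y_inf - (y_inf - y0) exp(-d/lambda)
#>   y0 = 0.2401, y_inf = 0.6466, lambda = 269.6 um, boundary = 807.5 um
#>   r2 = 0.990, n = 18, lambda identifiable
```

The decay fit recovers the generating decay length (true λ = 250 µm) and
places the boundary of effect — the distance at which the Amide I height
has recovered 95 % of its lumen-to-asymptote span — around 750–800 µm.
Near the lumen the normalized Amide I height sits near
0.35 × 0.65 ≈ 0.23 (degraded), far from it near 0.65 (intact).

The numbered scripts under `analysis/` run the full synthetic study
(7 NaOCl teeth × 4 quadrants × 18 points, 1 control) and write their
tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # spectra + manifest + indentation + morphometry
Rscript analysis/02_features.R     # preprocessing, descriptors, QI filter
Rscript analysis/03_quality_trend.R
Rscript analysis/04_gradient.R     # binned coefficients, decay fit, boundary
Rscript analysis/05_indentation.R  # bin summary, ANOVA, Welch, log trends
```

Stage 4, for example, prints the per-bin Amide I area coefficients
(5.50 per 100 µm in the first 100 µm, falling monotonically to 0.12 in
the 800–900 µm bin) and the pooled decay fit (λ = 247 µm, boundary
740 µm, r² = 0.985); stage 5 reports the test-group ANOVA
(F(8, 495) = 40.5, p < 10⁻⁴⁸) and the near-lumen test–control difference
(5.9 µm, p ≈ 3·10⁻⁶).

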