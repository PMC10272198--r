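# serafir

Chemometric case–control classification of serum ATR-FTIR spectra.

Mid-infrared spectroscopy of blood serum is an inexpensive, label-free way to
screen for disease: the 1800–900 cm⁻¹ "biofingerprint" region carries
absorption bands of proteins (amide I/II), nucleic acids, lipids and
carbohydrates, and subtle class differences in those bands can separate
patients from controls when combined with multivariate analysis. `serafir`
implements the standard chemometrics pipeline used for such studies — here
motivated by discriminating osteosarcopenia (combined loss of bone density
and muscle mass in older adults) from healthy controls — as a tested,
tidyverse-native R package for spectroscopists and chemometricians.

## The pipeline

Given replicate absorbance spectra **X** (rows = spectra, columns =
wavenumbers, descending):

1. **Preprocessing** — Savitzky–Golay smoothing (5-point window, order-2
   polynomial), automatic-weighted least squares (AWLS) baseline correction
   (iteratively reweighted polynomial fit that screens points above the
   baseline), truncation to 1800–900 cm⁻¹, replicate averaging, and
   mean-centering fitted on the training partition only.
2. **Splitting** — the deterministic Kennard–Stone max–min algorithm selects
   70 % of samples for training; venetian-blinds folds (sample *i* → fold
   *i* mod 10) drive all cross-validated choices.
3. **Reduction / selection** — either PCA, `X = TPᵀ + E` with orthonormal
   loadings **P** and scores **T** used as classifier inputs, or the
   successive projections algorithm (SPA), which builds minimally collinear
   variable chains by orthogonal projection and scores every chain prefix
   with the Mahalanobis cost
   `G = (1/Nᵥ) Σₙ r²(xₙ, m_true) / r²(xₙ, m_closest-wrong)`.
4. **Classification** — non-Bayesian discriminant scores
   `L_ik = (xᵢ − x̄ₖ)ᵀ C_pooled⁻¹ (xᵢ − x̄ₖ)` (LDA) and the per-class-covariance
   analogue (QDA), assigning the argmin class; or a soft-margin SVM with RBF
   kernel `K(x, z) = exp(−γ‖x − z‖²)`, its dual solved by a deterministic
   SMO routine and `(C, γ)` tuned on a log lattice by venetian-blinds CV.
5. **Validation** — confusion counts on the untouched test partition and the
   five figures of merit: accuracy, sensitivity, specificity,
   F-score = harmonic mean(SENS, SPEC) and G-score = geometric
   mean(SENS, SPEC); plus prominence-based peak picking on the first PCA
   loading to name the wavenumbers driving the separation.

Because serum cohorts of this kind are rarely public, the package ships a
seeded synthetic-cohort generator (`simulate_cohort()`) that emulates the
study design end to end: 32 control + 30 case samples in triplicate, with
class-discriminative Gaussian bands planted at 1711, 1661, 1574, 1510, 1398,
1273, 1225, 1107 and 906.5 cm⁻¹ over per-sample polynomial baseline drift
and replicate noise.

## Worked example

```r
library(serafir)

cohort <- simulate_cohort(cohort_config(), seed = 42)
run <- run_pipeline(cohort$spectra)
run
#> <ftir_run>
#>   62 samples (43 train / 19 test), 451 wavenumbers
#> # A tibble: 6 x 7
#>   model      ac  sens  spec    fs    gs best
#>   <chr>   <dbl> <dbl> <dbl> <dbl> <dbl> <lgl>
#> 1 pca-lda   100   100   100   100   100 TRUE
#> 2 pca-qda   100   100   100   100   100 FALSE
#> 3 pca-svm   100   100   100   100   100 FALSE
#> 4 spa-lda   100   100   100   100   100 FALSE
#> 5 spa-qda   100   100   100   100   100 FALSE
#> 6 spa-svm   100   100   100   100   100 FALSE
#>   PC1 loading peaks (cm^-1): 1710, 1660, 1574, 1510, 1398, 1272, 1226, 1106, 906
```

Reading the output: the Kennard–Stone split put 43 of the 62 samples in
training and 19 in test; every model classifies the held-out test samples
perfectly (all merits 100 %) because the planted band amplitudes are five
times the noise level — a deliberately separable default. The picked peaks
of the first loading (which captures ~91 % of the variance here) land on
the nine planted centers to within one 2 cm⁻¹ grid step, i.e. the pipeline
points at the right chemistry. With
`cohort_config(effect_bands = osteo_effect_bands(scale = 0))` the classes
are exchangeable and test accuracy collapses to chance, as it should.

Each stage is also exposed on its own (`preprocess_spectra()`,
`kennard_stone()`, `fit_pca()`, `spa_select()`, `fit_discriminant()`,
`fit_svm()`, `figures_of_merit()`, `peak_pick()`), with broom-style
`tidy()`/`glance()` methods and `autoplot()` for cohorts, loadings and run
reports.

## Package layout

- `R/synthetic.R` – seeded cohort generator; `R/io.R` – wide-CSV dialect
- `R/preprocess.R` – smoothing, AWLS baseline, truncation, averaging,
  centering
- `R/split.R` – Kennard–Stone and venetian blinds
- `R/pca.R`, `R/spa.R` – feature reduction and variable selection
- `R/discriminant.R`, `R/svm.R` (+ `src/smo.cpp`) – classifiers
- `R/metrics.R`, `R/peaks.R` – figures of merit, peak picking
- `R/pipeline.R` – `run_pipeline()` orchestration
- `vignettes/serum-ftir-classification.Rmd` – methods and design notes
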