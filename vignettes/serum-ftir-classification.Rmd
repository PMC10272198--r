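---
title: "Classifying serum ATR-FTIR spectra: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying serum ATR-FTIR spectra: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`serafir` implements a complete chemometric case–control pipeline for
attenuated total reflection Fourier-transform infrared (ATR-FTIR) spectra of
biofluids: preprocessing, Kennard–Stone splitting, PCA or SPA feature
handling, Mahalanobis discriminants or an RBF support vector machine, and
confusion-based figures of merit. This vignette explains the model behind
each stage, the tunable parameters and their defaults, the synthetic cohort
the package uses to validate itself, and the numerical decisions a
maintainer should know about.

## The data model

A spectral dataset is a wide tibble: `sample_id`, `replicate_id`,
`class_label` (`control`/`case`), then one numeric column per wavenumber in
cm⁻¹, strictly descending (the FTIR plotting convention; ascending files are
canonicalised on read). Replicates are physical re-measurements of the same
serum deposit: they share the sample's biology and baseline but have
independent detector noise, which is why the pipeline averages them only
*after* per-replicate preprocessing.

## Preprocessing

The chain is fixed, in this order, and entirely deterministic:

1. **Savitzky–Golay smoothing** (`sg_window = 5`, `sg_polyorder = 2`): each
   point is replaced by the value of the least-squares quadratic fitted over
   its 5-point window. At the spectrum edges the nearest full window is used
   and the polynomial evaluated at the edge offsets, so no data are
   fabricated and the output length equals the input length. Any polynomial
   of degree ≤ 2 passes through unchanged. The filter is delegated to
   `signal::sgolayfilt`, whose edge handling is exactly this rule; the test
   suite cross-checks it against an explicit per-window regression oracle.
2. **AWLS baseline correction** (`awls_order = 2`, `awls_tol = 1e-6`,
   `awls_max_iter = 100`): an order-2 polynomial is fitted to the spectrum,
   points above the fit are screened from pulling it up, and the fit is
   repeated until the coefficient vector is stable in relative ℓ₂ norm. The
   default *binary* screen clips the fit target of above-baseline points to
   the current baseline. This is the numerically tame formulation of
   zero-weighting: refitting only the surviving points lets the support set
   oscillate between iterations and, on unlucky noise, collapse onto a few
   extreme points with an unbounded fit, whereas the clipped-target
   iteration is a monotone contraction with the same fixed point on clean
   peak-plus-polynomial input (a pure polynomial is reproduced exactly; a
   planted Gaussian's apex survives to within 2 %). A *soft* screen
   (`exp(-r/s)` weights on positive residuals) is available by
   configuration. On noisy spectra the iteration approaches its fixed point
   geometrically but slowly; with the default cap of 100 iterations the
   remaining baseline drift is a smooth ~0.003 a.u. shape that is reported
   through the `converged` flag and simply joins the within-class variance.
   Baseline fitting happens on the full supplied grid, before truncation,
   because the fit benefits from the wider support; where the correction
   belongs relative to truncation is a genuinely open choice and this one is
   recorded here.
3. **Truncation** to the biofingerprint region (`region = c(1800, 900)`,
   inclusive): the window that contains the informative biomolecular bands
   while excluding the water-dominated and sparse regions.
4. **Replicate averaging**: arithmetic mean per sample, shrinking replicate
   noise variance by 1/n. Classes must agree within a sample.
5. **Mean-centering**, fitted on the *training* rows only and applied with
   those means to the test rows. Centering on all rows would leak test
   information into every model; the package refuses the temptation.

Normalisation variants (vector, SNV, min–max) are deliberately absent from
the default chain — on data of this kind they tend to trade away accuracy —
and are out of the package's validated surface.

## Splitting and cross-validation

`kennard_stone()` is the classical deterministic max–min selector: seed with
the two most distant samples (Euclidean distance on the preprocessed,
replicate-averaged, *uncentered* spectra), then repeatedly add the sample
farthest from the selected set, until `round(0.7 · n)` training samples are
chosen (rounding half away from zero; 62 samples → 43 train / 19 test). All
ties break to the lowest row index, making the split a pure function of the
data. The split is unstratified — with near-balanced classes the training
set stays mixed.

`venetian_blinds(n, k = 10)` assigns sample *i* (dataset row order) to fold
`((i − 1) mod k) + 1`. Every model-complexity choice — number of principal
components (over `pc_range`, default 1–10), SPA variable count, and the SVM
`(C, γ)` lattice point — maximises mean fold accuracy under these folds,
with ties resolved toward the smaller model (fewest components/variables,
then smallest `C`, then `γ`).

One pragmatic note: for component-count selection the PCA basis is fitted
once on the full training partition and fold accuracies are computed on its
scores, the usual chemometrics shortcut; the test partition plays no role in
any of it.

## PCA and SPA

`fit_pca()` decomposes the centered training matrix by SVD, `X = TPᵀ + E`;
explained-variance fractions are `σⱼ²/Σσᵢ²`, and each loading's sign is
fixed so its largest-magnitude element is positive (making the model
unique). Peaks of the first loading, picked by topographic prominence
(`peak_pick()`, default threshold 10 % of the maximum absolute loading),
name the wavenumbers that drive the dominant variance direction.

`spa_select()` is the classical successive projections algorithm: from every
starting variable, repeatedly append the variable whose column has maximal
norm after orthogonal projection off the span of the chain so far — chains
of minimally collinear variables. Every chain prefix is then scored on a
held-out validation set by the Mahalanobis cost
`G = mean(r²(xₙ, own mean) / r²(xₙ, closest wrong mean))` under the pooled
training covariance; the minimal-G subset wins. The validation set is carved
from the *training* partition by an inner Kennard–Stone 70/30 split, so SPA
never sees test data. `run_pipeline()` additionally lets venetian-blinds CV
choose among the per-size best subsets, reconciling the G criterion (which
ranks subsets) with the convention that model size is a cross-validated
choice.

Covariances anywhere in the package are ridged as `C + λI` with
`λ = 10⁻⁸·tr(C)/p` only when the condition number exceeds 10¹⁰ — raw
high-dimensional spectral covariances are routinely singular — and the λ
actually applied is recorded on the model.

## Classifiers

LDA and QDA use the *non-Bayesian* distance scores
`L = (x − x̄ₖ)ᵀ C_pooled⁻¹ (x − x̄ₖ)` and `Q = (x − x̄ₖ)ᵀ Cₖ⁻¹ (x − x̄ₖ)`:
argmin over classes, no prior or log-determinant terms. This differs from
textbook Gaussian-posterior QDA (which adds `log|Cₖ|`), and it makes the two
models coincide exactly whenever the per-class covariances are equal — an
identity the tests assert to 10⁻¹⁰. The positive class is the disease class
(`"case"`), so sensitivity reads as the case-detection rate.

The SVM solves the standard soft-margin dual with RBF kernel by sequential
minimal optimisation in compiled code: second-order working-set selection
(maximal violator paired with the partner of greatest predicted objective
decrease, ties to the lowest index), stopping when the KKT gap `m − M`
falls below 10⁻⁵ for final fits. Model-selection sweeps use 10⁻³, the
customary tuning tolerance, because extreme lattice corners (e.g.
`C = 2¹⁵` on nearly inseparable folds) are expensive to polish and fold
accuracies do not depend on the last digits of the dual. Two numerical
guards matter in practice: alphas are snapped to the box when within
`10⁻¹²·C` of a bound (a rounding residue there leaves a dead pair in the
working sets), and the margin vector is recomputed from scratch every 8192
iterations to shed incremental-update drift. The bias is the mean of
`yᵢ − f(xᵢ)` over unbounded support vectors; `sign(0)` predicts the
positive class by documented convention. The default tuning lattice is
`C ∈ 2⁻⁵…2¹⁵`, `γ ∈ 2⁻¹⁵…2³`, each stepping ×4.

## Figures of merit

From test-set confusion counts: accuracy, sensitivity and specificity as
percentages, and F-score (harmonic mean) and G-score (geometric mean) of
the *unrounded* SENS/SPEC pair. Display tables round half away from zero to
integer percent. The mean inequalities FS ≤ GS ≤ (SENS+SPEC)/2, with
equality exactly at SENS = SPEC, hold by construction and are asserted over
random tables. The best model is flagged by maximal accuracy, ties broken
by G-score — a rule the package states because it must pick something
deterministic.

## The synthetic cohort

`simulate_cohort()` generates the validation cohort the package's own
acceptance checks run on: 32 control and 30 case samples, three replicates
each, on an 1800→900 cm⁻¹ grid at 2 cm⁻¹ (451 points; a full 4000→600
acquisition grid is one configuration change away, and the analysis then
truncates it). Each replicate is

> Σ base bands + (case only) Σ effect bands + per-sample polynomial
> baseline + i.i.d. Gaussian noise.

Bands are Gaussian — the simplest localized line shape; nothing downstream
depends on the exact profile. The ten base bands sketch deproteinised serum
(amide I/II, CH deformations, amide III/phosphate, carbohydrates). The nine
effect bands sit at 1711, 1661, 1574, 1510, 1398, 1273, 1225, 1107 and
906.5 cm⁻¹ with amplitude deltas of 0.015–0.030 a.u.; protein- and
nucleic-acid-associated bands are lower in cases and lipid/phosphate bands
higher, matching the direction such differences take in serum studies of
musculoskeletal disease. `noise_sd = 0.003` a.u. puts the smallest effect
at 5× the noise level — a deliberately detectable regime, chosen once so
that pipeline properties (separability, peak recovery, null behaviour) are
crisply testable; no per-class variance or signal-to-noise figure exists to
calibrate against, so no claim is made that effect sizes match any real
cohort. Baseline coefficients (order ≤ 3 on the scaled coordinate) have
standard deviations (0.02, 0.01, 0.004, 0.002), drawn once per sample and
shared across its replicates so replicate averaging is meaningful; the
order-2 AWLS correction removes most of it, and the surviving cubic residue
is a realistic nuisance. Seeding is hierarchical (global seed → per-sample
stream → per-replicate stream), so enlarging a cohort never perturbs
existing samples and identical seeds give bit-identical data.

What the generator does *not* emulate: atmospheric water-vapour/CO₂ lines,
the wavelength dependence of ATR penetration depth, Mie scattering,
inter-subject biological variance beyond baseline drift, and instrument
drift between sessions. Passing tests on this cohort therefore demonstrate
that the pipeline's machinery is correct and statistically honest (signal
in → found; no signal in → chance accuracy), not that any particular
accuracy will transfer to real serum.

## Validation studies built into the package

The test suite runs, at fixed seeds and the study's own design sizes
(62 samples, triplicates, 451 wavenumbers; 20 Monte-Carlo seeds for the
statistical checks):

- exactness of the figure-of-merit arithmetic on benchmark integer
  sensitivity/specificity pairs;
- recovery of ≥ 7 of the 9 planted band centers within ±8 cm⁻¹ by the first
  loading's picked peaks in at least 15 of 20 seeds (observed: 9/9 in all
  20);
- mean PCA-SVM test accuracy ≥ 0.85 on planted-effect cohorts (observed:
  1.00) and, on null cohorts, within three Monte-Carlo standard errors of
  0.5;
- oracle equivalence: SPA against exhaustive chain-prefix search,
  Savitzky–Golay against per-window regression, Kennard–Stone against
  brute-force max–min, and the SMO dual against libsvm predictions with an
  independent KKT audit;
- analytic identities: QDA→LDA reduction, zero self-distance, the
  harmonic ≤ geometric ≤ arithmetic ordering, full-rank PCA reconstruction.

`scripts/acceptance.R` re-derives the headline quantities from scratch under
a caller-supplied seed.

## Known limitations

- The AWLS formulation is *a* reasonable reading of "automatic weighted
  least squares"; commercial implementations are proprietary and no
  numerical equivalence with them is claimed — only the invariant behaviour
  documented above.
- With the default iteration cap the AWLS `converged` flag is typically
  `FALSE` on noisy spectra; the truncation residue is small and smooth, but
  users wanting formal convergence should raise `awls_max_iter` (≈ 1500
  iterations suffices at these noise levels).
- Binary classification only; no probability calibration, ROC analysis, or
  multiclass schemes.
- Band *assignment* (naming the biomolecule behind a wavenumber) is a
  literature lookup, not a computation, and is out of scope.
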