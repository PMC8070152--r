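---
title: "Radiomic texture CADx for CESM lesion ROIs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic texture CADx for CESM lesion ROIs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cesmrad)
```

## The problem

Contrast-enhanced spectral mammography (CESM) produces, for each breast, a
low-energy image (LE, morphologically comparable to a standard 2D
mammogram) and a recombined image (RC, the digital subtraction that
highlights contrast uptake and hence neoangiogenesis). Radiologists draw a
box — a region of interest (ROI) — around each suspicious lesion on both
views. `cesmrad` implements a computer-aided diagnosis (CADx) pipeline that
maps such an LE/RC ROI pair to a malignancy score:

1. **Feature extraction** — 464 radiomic features in five sets;
2. **Per-set dimension reduction** — correlation-matrix PCA with an
   explained-variance retention rule;
3. **Model selection and evaluation** — greedy forward selection of
   principal components, scored by the median AUC of a classifier under
   repeated stratified 10-fold cross-validation, with operating points set
   by Youden's index.

The unit of analysis is the ROI, not the patient: a patient may contribute
several ROIs (grouped fold assignment by patient is possible via the
manifest's `patient_id` but is not the default, matching the protocol the
pipeline reproduces). BIRADS classes 2–3 define the benign label, 4–5 the
malignant label.

## The five feature sets

All features are computed per image (LE and RC separately); the two crops
are never registered or combined pixelwise, and their dimensions may
differ.

* **STAT (22 = 11 × 2 views).** First-order gray-level statistics: mean,
  standard deviation and their ratio, variance, skewness, entropy, relative
  smoothness, kurtosis, minimum, maximum, and max − min. Moments use the
  population convention (divide by *N*); the sample alternative is a
  one-line change in `population_moments()`. Entropy is in bits from the
  native integer histogram. Relative smoothness is
  $R = 1 - 1/(1+\sigma^2)$ with $\sigma^2$ computed on intensities rescaled
  to $[0,1]$ by $2^{\text{bit depth}}-1$, the standard normalization that
  keeps $R \in [0,1]$. Degenerate conventions (documented, not errors):
  a constant ROI has skewness, kurtosis and mean/std ratio defined as 0.
* **COUNT (10 = 5 × 2).** Keypoint counts from five detectors run on the
  contrast-stretched 8-bit image: a SIFT-style difference-of-Gaussian
  extremum detector (2 octaves, 3 intervals, contrast threshold 0.03, edge
  ratio 10), Shi–Tomasi minimum-eigenvalue corners (Sobel structure tensor,
  Gaussian window σ = 1.5, quality 0.01, 3×3 non-max suppression), FAST-9
  segment-test corners (threshold 20 gray levels), a BRISK-style
  multi-scale FAST (3 pyramid layers), and MSER blobs (threshold sweep with
  Δ = 5, max variation 0.25, area in [20, 0.4·*n*], both polarities). The
  detectors are implemented in the package with these parameters frozen;
  only the counts are used, never descriptors, and counts are raw (not
  normalized by ROI area).
* **GRAD (24 = 6 × 2 maps × 2).** Mean, variance, skewness, entropy,
  relative smoothness and kurtosis of the Sobel gradient magnitude and
  direction. Boundary handling is half-sample symmetric padding. Direction
  is `atan2(Gy, Gx)` treated as a plain real in $(-\pi,\pi]$ — no circular
  statistics. For continuous-valued maps, entropy uses 256 equal-width bins
  over the observed range and relative smoothness normalizes by the
  observed range (a flat map gives 0 for both).
* **HAAR (96 = 6 × 8 bands × 2).** The same six statistics on the
  coefficients of a two-level orthonormal Haar decomposition
  (LL1, HL1, LH1, HH1 and, re-decomposing LL1, LL2, HL2, LH2, HH2). Odd
  dimensions are symmetrically extended by one sample; on even sizes the
  transform conserves energy exactly, which the tests assert.
* **GLCM (312 = 13 × 4 directions × 3 bands × 2).** Thirteen co-occurrence
  descriptors (contrast, correlation, cluster prominence, cluster shade,
  dissimilarity, energy, entropy, homogeneity, sum average, sum variance,
  sum entropy, difference entropy, normalized inverse difference moment) on
  the three first-level Haar *detail* bands (HL1, LH1, HH1), four offset
  directions (0°, 45°, 90°, 135°) at distance D = 2, after equal-width
  quantization of each band to 8 levels over its own min–max range.
  Matrices are accumulated symmetrically and normalized to joint
  probabilities before descriptor computation (the Haralick convention);
  entropies are in bits and level indices run 1..8 in the moment-style
  sums. The choice of the three detail bands is forced by the set's
  cardinality: 13 × 4 × 3 × 2 = 312, whereas including LL1 would give 416.
  A band that quantizes to a single level yields the constant-band closed
  forms (energy 1, entropy 0, contrast 0, correlation defined as 0 because
  the marginal variance vanishes) rather than NaNs.

The minimum ROI side of 8 pixels, enforced at load, guarantees non-empty
second-level Haar sub-bands and valid distance-2 co-occurrence offsets.

## PCA reduction

Each set is standardized feature-wise (mean 0, sd 1, denominator $n-1$) and
the eigen-decomposition of the correlation matrix $R$ taken: the *k*-th
principal component is $y_k = Z\gamma_k$ with variance $\lambda_k$, the
*k*-th largest eigenvalue. When a set has more features than there are ROIs
(GLCM's 312, HAAR's 96), the decomposition is computed through the SVD of
$Z$, which yields the identical nonzero spectrum without forming the
312 × 312 matrix. Numerical conventions: zero-variance features are dropped
with a warning before standardization; eigenvector signs are fixed so each
component's largest-magnitude loading is positive (needed for reproducible
loading reports); eigenvalues sum to the number of retained features (the
trace of $R$), which the tests assert to 1e-8.

Retention uses the explained-variance criterion with threshold 0.8: the
smallest $p$ whose cumulative proportion strictly exceeds the threshold.
Loading inspection (`important_loadings`) reports at most 5 features per
component whose loading magnitude is at least 0.25 of the component's
maximum — the floor makes "coefficients close to zero" concrete while
reproducing 4–5 features per component in typical reports.

Two evaluation modes exist because the original protocol is ambiguous about
where PCA sits relative to cross-validation:

* `per_fold` (default): the PCA of every set is refit on the training rows
  of each fold and held-out rows are projected with the training
  standardization. No information from the held-out fold reaches the
  transform. This is the statistically defensible mode and the default.
* `global`: PCA fit once on all rows, components then cross-validated.
  This reproduces the apparent original protocol but lets the unsupervised
  transform see test rows: each candidate component becomes a fixed score
  column whose accidental correlation with the labels persists across
  every round, so on null data the combination of global PCA and greedy
  selection inflates the best median AUC well beyond the per-fold mode's.
  That is why it is not the default.

## Classification and selection

Three classifiers, hyperparameters frozen before any CV and identical
across candidate subsets:

* **RF** — random forest, 100 trees, Gini split criterion,
  $\lfloor\sqrt{p}\rfloor$ variables per split (via `randomForest`); the
  score is the fraction of trees voting malignant.
* **NB** — Gaussian naive Bayes with per-class variance floors of 1e-9 so
  a component that is constant within a small training fold cannot produce
  infinities; the score is the posterior probability of malignancy. (The
  floor is why this is implemented in-package; it agrees with
  `e1071::naiveBayes` to 1e-6 on well-behaved data, which a test checks.)
* **GLM** — logistic regression, unpenalized where the design is full rank,
  with a tiny-ridge (1e-6) Newton fallback for rank-deficient or separable
  folds; the score is the sigmoid output.

**Cross-validation.** Folds are stratified by class — with 15 benign among
58 ROIs, unstratified 10-fold splits frequently produce single-class
folds — and re-randomized each round from a counter-derived seed, so the
whole evaluation is a pure function of (data, configuration, base seed).
Per round, out-of-fold scores are pooled over the 10 folds; the round's AUC
(Mann–Whitney, ties counted ½) and its Youden operating point are computed
on that pooled vector; medians (and the AUC IQR) are reported across
rounds. The Youden threshold maximizes $J = \text{sens} + \text{spec} - 1$
over midpoints between adjacent distinct scores plus ±∞, classifying as
malignant where score > threshold; $J$ ties break by accuracy, then by the
lower threshold; an all-equal score vector returns the degenerate threshold
with a warning.

**Forward selection.** Starting from the single component with the highest
median AUC, the component that maximizes the grown model's median AUC is
added at each step; ties break by the higher 25th-percentile AUC, then the
lower candidate index. The best subset is the argmax of median AUC along
the path, ties to the smaller subset. All candidate evaluations share the
same fold seeds, so comparisons are paired. Because each step costs a full
repeated CV per remaining candidate, `max_steps` can cap the path; the
reported best subset is then the best within that horizon, which can only
understate the maximum — relevant here because best models in this domain
use two or three components.

## The phantom generator

Clinical CESM ROIs cannot ship with the package, so `phantom_config()` /
`generate_phantom_dataset()` synthesize seeded LE/RC pairs whose two
classes differ exactly in the statistic families the extractors measure.
The texture is an FFT-filtered Gaussian random field with power-law
spectrum $|f|^{-\beta}$; a parametric anisotropic Gaussian blob is
superposed on the RC view (weak and smooth for the benign class); pixel
noise is added and the result quantized to 8 bits. With class separation
$s \in [0,1]$ the malignant class has exponent $\beta = 3 - 1.6s$ (shorter
correlation length, more high-frequency texture), contrast $12 + 10s$ gray
levels, RC blob amplitude $25 + 70s$ with a sinusoidal boundary
perturbation of relative depth $0.45s$ (irregular margin). At $s = 0$ the
two classes are drawn from the same distribution, which is what makes the
null-calibration check meaningful. Defaults (64×64 pixels, noise sd 5,
15 benign / 43 malignant mirroring the clinical class balance) were chosen
once as plausible desk-scale conditions. One top-level seed spawns
per-lesion substreams by counter, so growing a dataset preserves its
prefix.

What the phantoms do **not** emulate: scanner physics (no PSF, no dose or
detector noise model), anatomy (no parenchymal background, no calcifications),
radiologist variability in ROI placement, and any LE/RC physical coupling.
Passing the pipeline's acceptance checks on phantoms therefore demonstrates
that the machinery measures and recovers the intended statistical
structure — not clinical performance. The clinical numbers of the original
study are functions of a private 58-ROI dataset and are not reproduced
here.

## Problem sizes used by the shipped checks

The acceptance checks run the full pipeline at desk scale, chosen to keep
the whole suite within minutes while leaving the conclusions unambiguous:
60 phantoms (15/45), 20 rounds of 10-fold CV, pooled forward selection
capped at 6 steps, and 10 replicates of the planted-component recovery
simulation at $n = 100$. At these sizes the separated-class arm saturates
(median AUC 100%) and the null arm's best median AUC stays near 72% —
comfortably away from both the 95% signal requirement and, for the null,
below the 75% optimism guard. The guard value is an empirical convention:
greedy selection over ~47 null candidates at $n = 60$ legitimately drifts
above chance, and the check exists to ensure that this optimism is not
mistaken for signal.

## Known limitations

* Keypoint detectors are faithful to the published detector *families* but
  are this package's implementations; absolute counts will differ from
  OpenCV/MATLAB implementations. They are deterministic, parameterized, and
  validated on constructed fixtures (corners of a square, flat fields).
* Direction statistics ignore circularity; a gradient direction of $-\pi$
  and $\pi$ are the same angle but count as distribution extremes.
* The GLCM set's band choice (three first-level detail bands) resolves a
  cardinality ambiguity in its source; including LL1 would change the count.
* `per_fold` PCA makes component *indices* (not loadings) the unit of
  selection: "HAAR_PC2" is the second-largest-variance direction of each
  training fold, which may rotate between folds when eigenvalues are close.
* DICOM ingest is not provided; export ROIs to PNG/TIFF first.
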