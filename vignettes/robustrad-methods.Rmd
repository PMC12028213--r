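---
title: "Robust radiomics of DCE- and DW-MRI: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust radiomics of DCE- and DW-MRI: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(robustrad)
```

# The problem

Radiomic classifiers built on quantitative MRI are fragile in two specific,
well-understood ways.  First, texture features are sensitive to exactly
where the region of interest (ROI) is drawn: two radiologists segmenting
the same parotid lesion produce feature vectors that can differ more than
the tumor classes do.  Second, when thousands of features are winnowed to a
handful *before* cross-validation, the apparent accuracy of any downstream
classifier is optimistically biased — the selection step has already seen
the test data.  `robustrad` implements a pipeline that addresses both:
features are screened for reproducibility under systematic ROI
perturbation, and all selection and tuning happen strictly inside the
cross-validation loop.

Because the kind of clinical data this targets (dynamic contrast-enhanced
and multi-b-value diffusion MRI of salivary-gland tumors) is rarely
shareable, the package ships a synthetic phantom cohort generator with
known ground truth, so that every stage — curve fitting, feature
extraction, the reproducibility gate, the nested classifier — is testable
end to end without patient data.

# Signal models

## DCE: semi-quantitative descriptors and the extended Tofts model

The DCE series is one pre-contrast volume plus ten post-contrast volumes at
38-second resolution.  Per voxel, the relative enhancement is
$E(t) = (S(t) - S_0)/S_0$ with $S_0$ the pre-contrast intensity.  Six
model-free descriptors summarise the curve: maximum relative enhancement
(MRE, %), time to peak (TTP, seconds from the first post-contrast frame),
wash-in slope (WIS = MRE/TTP, %/s), wash-out slope (WOS, the chord from
peak to the final frame, %/s), wash-out ratio
(WOR = $(E_{peak}-E_{last})/E_{peak}$, clamped to $[0,1]$) and the
wash-in/wash-out ratio WIO = WIS/WOS.  The literature names these
descriptors without fixing formulas; the chord definitions used here are
the simplest reproducible reading, and all conventions are frozen in the
documentation of `model_free_maps()`.  Three edge cases are handled
explicitly: the peak search is restricted to post-contrast frames; when
the peak *is* the first post-contrast frame the wash-in chord is taken
from the pre-contrast frame (avoiding division by zero); and curves with
no washout get `WIO = 0` when flat, or a finite sentinel (default `1e6`,
QC-counted) when persistently enhancing, so parametric maps never carry
infinities into feature extraction.

The model-based maps come from the extended Tofts model,

$$C_t(t) = K^{trans}\int_0^t C_p(\tau)\,e^{-k_{ep}(t-\tau)}\,d\tau + v_p\,C_p(t),
\qquad k_{ep} = K^{trans}/v_e,$$

with $K^{trans}$ (min$^{-1}$) the transfer constant, $v_e$ the
extravascular-extracellular volume fraction and $v_p$ the plasma volume
fraction.  Since no T1 mapping is part of the acquisition, fitting operates
on relative enhancement under a linear signal model $E(t) = \alpha C_t(t)$
with configurable $\alpha$ — the standard low-concentration
spoiled-gradient-echo approximation.  The default $\alpha = 3$ puts peak
lesion enhancement near 80% for typical simulated kinetics, consistent
with strong T1-weighted tumor enhancement at a 0.1 mmol/kg dose; at
$\alpha = 1$ the phantom's enhancement amplitude (~27%) is so small
relative to the 2% noise floor that even maximum-likelihood fitting cannot
estimate $K^{trans}$ to within 10%.

**AIF.**  The plasma input $C_p(t)$ uses the classic Weinmann population
biexponential ($a_1 = 3.99$, $a_2 = 4.78$ kg/L; $m_1 = 0.144$,
$m_2 = 0.0111$ min$^{-1}$; dose 0.1 mmol/kg), multiplied by a short
bolus-arrival ramp $1-e^{-t/8\,\mathrm{s}}$ so that $C_p(0)=0$; a Parker
population AIF and a rectangular test bolus are also available.  A
population AIF is the only reproducible choice when no patient-specific
input is measured.

**Fitting.**  The convolution is evaluated on a fine uniform grid with an
unconditionally stable trapezoidal recursion.  The voxel fit exploits the
model's structure: at fixed $k_{ep}$, $C_t$ is *linear* in
$(K^{trans}, v_p)$, so the fit profiles a dense log-spaced $k_{ep}$ grid
(400 points over $10^{-5}$–$0.35$ s$^{-1}$) with an exact nonnegative
two-variable least squares at each grid point, then refines the optimum by
parabolic interpolation in $\log k_{ep}$.  This is deterministic,
seed-free, has no convergence failures in the usual sense, and recovers
noiseless simulated parameters to well under 1%.  Fitted $v_e, v_p$ are
bounded to $[0,1]$ and $K^{trans}$ capped at 2 min$^{-1}$ (noise-driven
background voxels otherwise produce arbitrarily large transfer constants);
bound-hitting voxels are QC-flagged.

## DWI: IVIM

The diffusion series covers 11 b-values (0–800 s/mm²).  The intravoxel
incoherent motion model with a separate pseudo-diffusion term is

$$S(b) = S_0\left[f\,e^{-bD^*} + (1-f)\,e^{-bD}\right],$$

stated explicitly because conventions differ (some authors use
$e^{-b(D+D^*)}$ for the perfusion term).  Fitting is segmented — the
standard strategy for this b-value distribution, which has a natural gap
above 100 s/mm²: a log-linear fit over $b \ge 200$ estimates $D$ and, via
the intercept, $f$; then $D^*$ comes from a one-dimensional bounded least
squares on the full biexponential.  A plain segmented fit leaves a few
percent of perfusion contamination in the $D$ estimate (at $D^* = 10^{-2}$
mm²/s the perfusion term still holds ~13% of its weight at $b=200$), so the
estimated perfusion signal is subtracted from the high-b segment and the
two steps repeated; eight refinement passes bring noiseless recovery of all
three parameters below 0.5%.  Bounds are $D \in [10^{-5}, 4\times10^{-3}]$,
$D^* \in [D, 0.5]$ mm²/s, $f \in [0,1]$; clipped or bound-pinned voxels are
QC-flagged ($D^*$ remains the ill-conditioned parameter under noise, which
is documented rather than hidden).

# ROI perturbation and the reproducibility gate

From each lesion mask, 15 artificial ROIs are generated: in-plane rotations
of ±10°, ±20°, ±30° about the mask barycenter, dilations with 3D
structuring elements of connectivity 1 (6-neighbour cross) and 2
(18-neighbourhood), a 1-voxel erosion, and 1-voxel translations along each
axis in both directions.  Rotation is applied slice-wise (the reading of
"axial rotation") about the (x,y) projection of the 3D barycenter in
physical coordinates, with bilinear interpolation of the binary mask and
re-binarisation at 0.5 — the standard recipe, fixed so results are
bit-stable.  Clockwise means a negative mathematical angle in the (x,y)
index plane viewed from +z.

Each of the 93 features on each of the 12 maps is then scored with the
intraclass correlation coefficient across the 16 ROI variants (original
included, configurable), treating lesions as subjects and variants as
raters.  The form is ICC(2,1) — two-way random effects, absolute agreement,
single measurement: perturbations are "raters" whose systematic offsets
matter, which rules out the consistency forms.  Negative estimates are
reported as computed but always categorised "poor"; a zero-variance matrix
is trivially perfect agreement (value 1, flagged).  Only features with
ICC strictly above 0.9 ("excellent" agreement) pass the gate.

# Feature extraction

93 features per parametric map, in six IBSI families: 18 first-order, 24
GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM, 14 GLDM; across the 12 maps (9 DCE + 3
DWI) a lesion contributes 1116 features named `[group]_[name].[MAP]`
(e.g. `glcm_Idmn.VP`).  No shape family is included and no image filtering
or resampling is applied — original-voxel features only.  Conventions,
fixed and shared with the independent reference implementation used in the
tests:

* fixed-bin-width discretisation anchored at the ROI minimum,
  `level = floor((v - min)/w) + 1`;
* symmetric GLCM and GLRLM over the 13 unique 3D directions, features
  computed per direction and averaged (directions with no voxel pair are
  skipped);
* 26-connectivity for GLSZM zones and for the GLDM/NGTDM neighbourhoods;
  GLDM dependence size includes the center voxel (α = 0);
* entropies in bits; population moments for skewness and kurtosis
  (kurtosis not excess-corrected).

Because the 12 maps live on wildly different scales (TTP in seconds, Ve in
[0,1]), a single bin width would be meaningless; per-map defaults
(`default_bin_widths()`) are chosen so typical lesion ranges discretise to
roughly 10–40 gray levels.  The texture kernels are implemented in C++ and
operate on the ROI bounding box, which makes the full 43 × 16 × 12
extraction a matter of minutes.

The primary correctness argument for this module is dual-route: an
independent numpy/scipy implementation of all 93 features ships in
`inst/oracle/ibsi_oracle.py`, and the test suite requires full-vector
agreement within $10^{-6}$ relative on 20 randomly generated ROIs.

# Nested selection and classification

The classification stage is deliberately strict about leakage.  A shared
fold plan (stratified 5-fold, repeated; `make_fold_plan()`) is drawn once
and reused by every selector × classifier pair, so performance differences
cannot come from fold luck.  Within each fold: features are standardised
by training-fold statistics; selection runs on the three-class labels
(adenoma / Warthin / malignant — the class structure carries the signal);
hyperparameters are tuned by an inner 3-fold CV on the training folds; the
held-out fold is predicted exactly once.  Reported metrics are binary
(malignant vs benign): accuracy, sensitivity (malignant recall) and
specificity, pooled per repetition, then summarised as means with 5th–95th
percentile intervals across repetitions.

Four selectors:

* **AUC** — mean orientation-corrected one-vs-one ROC AUC over the three
  class pairs; keep features with mean AUC strictly above 0.8.
* **ReliefF** — multi-class weights (k = 10 neighbours, misses weighted by
  class priors, Manhattan distance on range-scaled features); each
  feature's weight is compared with the 95th percentile of its own null
  distribution from 500 label permutations.  The per-feature null (rather
  than one pooled null) is a documented reading of an ambiguous rule;
  permutations only reshuffle labels, so the distance geometry is computed
  once (C++).
* **LASSO** — L1-penalised multinomial logistic regression with the
  penalty chosen by stratified inner CV; all features with nonzero
  coefficients are kept, with a single-feature fallback from the
  coefficient path if the chosen penalty shrinks everything away.
* **Backward elimination** — greedy removal maximising inner-CV LDA
  accuracy, stopping when every removal strictly hurts; ties break by
  feature name, making it deterministic.  Because the greedy sweep is
  quadratic in pool size, the pool is first reduced to the 15 features
  with the highest mean AUC — a tractability choice the package documents
  as its own (the original elimination strategy in this line of work is
  unspecified).

Four classifiers: LDA (no grid), k-NN ($k \in \{3,5,7,9,11\}$), radial SVM
(cost $\in \{0.25,\dots,4\}$), and a single-hidden-layer neural network
(size $\in \{1,3,5\}$, decay $\in \{0, 0.01, 0.1\}$, 200 iterations, seeded
per fit for determinism).  The grids are package choices; the tuned
parameters themselves follow standard practice.

The selection-bias rationale is made testable: `selection_bias_demo()`
contrasts the nested estimate with the biased protocol that selects
features once on the full data and then cross-validates only the
classifier.  On label-permuted data the nested estimate stays at chance
while the non-nested one is inflated — the package's regression test for
leakage.

# The synthetic phantom

`make_cohort()` emulates the study conditions: 43 lesions (15 pleomorphic
adenomas, 10 Warthin tumors, 18 malignant; 18 vs 25 for the binary task),
each an ellipsoid of 5–8 mm radii (≥ 1 cm diameter, the clinical inclusion
threshold) on a 64 × 64 × 32 grid at 1 × 1 × 3 mm — a deliberately reduced
matrix whose problem sizes keep a full desk run in minutes.  The DCE
forward model is baseline × (1 + αCt) with Gaussian noise (default σ = 2%
of baseline); DWI lesions follow the IVIM biexponential, the background a
perfusion-free monoexponential (D = 1.2 × 10⁻³ mm²/s).  Additive Gaussian
(rather than Rician) noise is a simplification adequate at this SNR; a
Rician option is a noted extension.

Per-class parameter distributions (`default_class_params()`) are **test
fixtures, not population claims**: adenomas get low Ktrans / high Ve /
high D (slow, persistent enhancement), Warthin tumors high Ktrans /
moderate washout / high perfusion fraction, malignant lesions an
intermediate Ktrans but the lowest Ve — hence the fastest washout rate
$k_{ep} = K^{trans}/v_e$ — together with high Vp and low D.  The design is
deliberate: the end-to-end check requires *every* selector × classifier
pair to exceed 0.9 accuracy on the phantom, which constrains the fixture
geometry in two ways.  Linear separability of malignant vs benign is
needed for LDA; and the malignant class must be *extreme*, not
intermediate, on most feature families that survive the reproducibility
gate — a nearest-neighbour vote over features where malignant sits between
the two benign clusters systematically misassigns malignant lesions no
matter how separable a minority of features is.  Giving malignant lesions
the fastest washout makes them extreme on the large semi-quantitative
washout family (WOS, WOR, WIO, TTP) rather than only on VP and D.  What
passing these tests shows is that the pipeline machinery is correct and
leak-free — not that real parotid tumors are this separable; real data add
partial-volume effects, motion, Rician noise, field inhomogeneity and
genuinely overlapping biology that the phantom deliberately omits.

One open bookkeeping point in the source material: the patient count is
stated as 41 while the class counts (10 + 15 + 18) and the binary split
(18 + 25) both total 43.  The cohort default follows the 43-lesion
arithmetic.

# Numerical choices and degenerate inputs

* Tofts fit: profiled grid + parabolic refinement (above); flat curves
  return $K^{trans} = v_p = 0$ without special-casing.
* IVIM: signals must be positive; constant signals pin $D$ at the lower
  bound and are flagged non-physiological.
* Maps are fitted over the union of all 16 ROI variants, so dilated,
  rotated and translated variants always index defined voxels; on the
  overlap this is identical to fitting each variant separately and far
  cheaper.
* Discretisation caps at 2000 gray levels with a hard error — a bin width
  grossly mismatched to a map's range is a configuration bug, not
  something to paper over.
* Single-voxel ROIs: first-order, GLRLM, GLSZM and GLDM are defined; GLCM
  and NGTDM raise a documented degenerate-input error.
* ICC on a zero-variance matrix returns 1 with a `degenerate` attribute.
* Fold plans deal classes round-robin from a random starting fold, so fold
  sizes are within ±1 overall and per class (43 lesions → 9/9/9/8/8).

# Problem sizes used by the automated checks

The package's own acceptance checks run the full default cohort (43
lesions × 16 variants × 12 maps = 8256 feature vectors) with 10 CV
repetitions — study-scale in every dimension except the repetition count,
where 100 repetitions reproduce the original protocol at proportionally
longer runtime (the repetition count only narrows the percentile
intervals; it does not change the estimates' means).  Parameter-recovery
checks use 100-voxel simulations at the acquisition's 2% noise design
point; the ICC oracle check uses 50 random subject × rater designs; the
null-calibration check uses 10 repetitions of 5-fold CV on label-permuted
phantom features.

# Known limitations

* The phantom has no anatomy, motion, coil bias or Rician noise floor;
  robustness numbers on it say nothing about scanner-to-scanner
  generalisation.
* $D^*$ is ill-conditioned at realistic noise; its errors are reported,
  not bounded.
* The linear enhancement–concentration assumption ignores T1 and
  saturation effects; $\alpha$ is a single global constant.
* ICC confidence intervals and inter-observer (two-radiologist) agreement
  are out of scope; the gate uses point estimates.
* With ~40 samples, nested CV estimates retain wide percentile intervals;
  that is a property of the design being emulated, not a defect of the
  implementation.
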