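---
title: "Methods: volumetric CNN screening of cerebral small vessel disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volumetric CNN screening of cerebral small vessel disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(voxcnn)
```

## The problem

Grade-1 cerebral small vessel disease (cSVD) shows radiologically as mild
white matter hyperintensity (WMH) burden: small bright lesions adjacent to
the lateral ventricles on T2-weighted and FLAIR MRI. voxcnn implements a
complete computer-aided screening pipeline for this binary decision
(diseased vs control) operating on raw per-patient DICOM slice series:

1. **Preprocessing** into a fixed-shape volume,
2. a compact **3D convolutional network** classifier,
3. a **split / augment / cross-validate** training protocol,
4. confusion-matrix and ROC **metrics**, and
5. **Grad-CAM** volumetric saliency for interpretability.

Because clinical MRI of this kind cannot be redistributed, the package also
ships a seeded **synthetic phantom cohort generator** that writes standard
DICOM series mimicking the statistical structure of a small clinical cohort
(45 patients, 30 diseased : 15 control). Every stage of the pipeline is
exercised and tested against these phantoms.

## Preprocessing model

A patient arrives as a directory of DICOM files: axial, sagittal and
coronal series of T1W, T2W and FLAIR sequences, with square pixel matrices
of 64, 256 or 512 (the 64×64 images are scout/localizer slices). The chain
is:

* **Sort** by the DICOM instance-number attribute (stable sort, so the
  pipeline is invariant to on-disk file order).
* **Group sequences** in the fixed order T1W < T2W < FLAIR. The source
  protocol pools all three sequences of one patient into a single stack
  without stating their interleaving; we chose deterministic
  sequence-major grouping, with acquisition order inside each sequence.
* **Filter** to axial T1W/T2W/FLAIR slices only.
* **Discard** matrices smaller than 128 pixels (scouts).
* **Resize** to 128×128 by exact area-weighted averaging (anti-aliased
  local-mean shrink; a constant image stays constant to machine
  precision, and a same-size input is returned bit-identically).
* **Normalize** each pixel by the pooled z-score `(x - mean) / sd`, using
  the *population* standard deviation (the formula carries no Bessel
  correction). By default the statistics are pooled over the **training
  patients only** and reused for validation/test; `stats_scope = "all"`
  reproduces pooling over the whole dataset, which leaks test-set
  intensity statistics and exists only for protocol fidelity.
* **Zero-pad** the depth axis to 120 slices, padding *after* the real
  slices. Normalizing before padding means the pad value 0 coincides with
  the cohort mean intensity. A patient with more than 120 qualifying
  slices is refused with an explicit error: the source protocol's maximum
  was 115 and no truncation policy is defined.

The result is always a `(120, 128, 128, 1)` tensor with the count of real
slices recorded. The reduced profile (below) uses `(24, 32, 32, 1)` with
the same chain.

## The classifier

Four convolutional blocks — Conv3D (kernel 3×3×3, stride 1, no padding,
ELU activation), channel-wise batch normalization, 2×2×2 max pooling —
with 8/16/32/64 filters, then flatten → dense(40, ELU) → dropout(0.2) →
dense(10, ELU) → dropout(0.2) → dense(1, sigmoid). Kernel size, stride and
padding are not stated in the source text; they are uniquely recoverable
from the published layer shapes and parameter counts (e.g. block 1:
`8·(3³+1) + 4·8 = 256` parameters and `120 → 118 → 59` per axis), and the
package enforces that reconstruction in its tests:

```{r}
print_model_table(architecture("paper"))
count_parameters(architecture("paper"))$total  # 534653
```

Other fixed choices, with rationale:

* **He initialization**, `Normal(0, sqrt(2/fan_in))`, zero biases.
* **ELU α = 1** (the formula is given without a value; 1 is canonical).
* **L2 coefficient 0.05** on every convolutional and dense weight tensor
  (not on batch-norm parameters, which the regularization statement does
  not cover); the penalty is exactly `0.05·Σw²` and its gradient `0.1·w`.
* **Batch normalization** uses batch statistics in training and running
  statistics (momentum 0.99, ε = 1e-3) at inference; the two running
  moments per channel are the model's 240 non-trainable parameters.
* **Decision threshold 0.5** for binary accuracy.

### The network engine

No automatic-differentiation runtime is available to this package, so the
forward *and* backward passes are implemented here: compiled (Rcpp)
kernels for the 3D convolution and max pooling, vectorized R for batch
normalization, dense layers, dropout and the Adam optimizer. Correctness
is pinned two ways: the convolution and pooling forward passes are checked
against direct sliding-window oracles, and the full loss gradient
(including the L2 term, through batch normalization in training mode) is
checked against central finite differences on a sub-1000-parameter profile
to ≤ 1e-4 relative error (measured ~1e-7).

## Training protocol

* 20 % of patients are held out as the test set first; the remainder is
  split 80/20 into training and validation. Stratification preserves
  class proportions within one patient. For the study's 45-patient cohort
  this yields 9 test, 29 train, 7 validation.
* The training pool is expanded by **augmented copies**: in-plane
  translation, shear, rotation or small affine maps applied slice-wise
  (bilinear, zero fill, so the padding contract is preserved). Magnitudes
  are not stated in the source and default to translation ≤10 % of the
  extent, shear ≤10°, rotation ≤15°, affine scale ±10 % with rotation
  ±10°. Two per-class policy presets exist: `"shear_balance"`
  (translation+affine on the control class, shear on both; with a 2:1
  imbalance, 30+30 vs 15+45 comes out balanced at 60/60) and
  `"rotation_affine"` (rotation on both, affine on the control class —
  the headline recipe). The two presets reflect the source's two
  inconsistent descriptions of the protocol; both are provided and
  neither is adjudicated.
* The protocol augments before the train/validation split, which can put
  an original and its augmented copy on opposite sides. `run_kfold()`
  therefore has a `group_by_patient` mode (default on) that keeps every
  copy of a patient in one fold; the protocol-faithful mode remains
  available.
* **Loss**: mean binary cross-entropy (probabilities clipped at 1e-7)
  plus the L2 penalty. **Optimizer**: Adam, learning rate 0.001, reduced
  ×0.5 after 5 stagnant epochs of monitored validation loss
  (reduce-on-plateau). Batch size and epochs are unstated in the source;
  defaults are 2 and 100, and the desk-scale runs below use 4 and 90 (at
  45 epochs the ranking is already perfect but the sigmoid outputs are
  under-converged and straddle the 0.5 threshold).
* **Cross-validation**: without augmentation, a 90/10 split with 6-fold
  CV inside the training set; with augmentation, a 80/20 split, class
  balancing, then stratified 5-fold CV. Per-fold metrics and their
  arithmetic mean are reported; undefined ratios (zero denominators) stay
  `NA` rather than being silently zeroed, so fold means are not
  corrupted.

## Metrics

Accuracy, precision and recall come from the thresholded confusion
counts. AUC is computed as the rank statistic (probability a random
positive outranks a random negative, ties counted ½), which equals the
area under the empirical ROC curve and is invariant under strictly
increasing score transforms. All five metrics are tested against
brute-force oracles (exhaustive pair enumeration for AUC, direct counting
for the ratios) over enumerated and sampled small label/score sets, and
AUC is additionally cross-checked against the pROC package.

## Grad-CAM

Relevance is computed at a convolutional block's output. The default is
the deepest block whose feature map keeps at least two cells along every
spatial axis — block 4, shape (5, 6, 6, 64), on the full profile; on the
reduced profile this rule selects block 2 (4×6×6), since the deepest
reduced block collapses to a single cell along depth and cannot localize.
Channel weights are the spatial means of the gradient of
the **pre-sigmoid logit** (standard practice — the probability's gradient
vanishes at saturation; the source is silent on this), the CAM is the
rectified weighted feature-map sum, upsampled trilinearly to the input
grid, and max-normalized over the **whole volume** rather than per slice
so that uninformative slices stay dark. Overlays render grayscale anatomy
with a red-yellow heat ramp; zero-padded slices render black.

## The phantom cohort

The generator is the package's stand-in for the private clinical data and
defines the study conditions for every test:

* 30 diseased : 15 control by default; per-patient **total** qualifying
  axial slice counts drawn uniformly from [23, 115]. (The per-patient
  total is the quantity the source bounds; a per-sequence draw would
  overflow the 120-slice stack.) The total is split across the enabled
  sequences; each sequence additionally gets two 64×64 scout slices and
  three sagittal/coronal slices exist per patient, all of which
  preprocessing must discard.
* Image content is stylized: an ellipsoidal head with per-sequence tissue
  and CSF intensities (T1W dark CSF, T2W bright CSF, FLAIR suppressed
  CSF), two ventricle ellipses near mid-depth, and — in diseased patients
  only — `lesion_count` hyperintense ellipsoidal lesions flanking the
  ventricles near mid-depth on T2W/FLAIR axial slices, brighter than
  tissue by the factor `lesion_contrast`, plus Gaussian pixel noise
  (σ = 20 on a 0–4095 scale). Lesions alternate ventricle sides with
  jittered offsets, reflecting the characteristically bilateral
  presentation of periventricular caps (independent side draws can place
  every lesion on one side, where they merge into a single blob — an
  atypical presentation that is also much harder to learn). The lesion
  depth radius is a fraction of the sequence block (`lesion_depth_frac`):
  0.10 for the full profile (~1.2 slice spacings at ~12 slices per
  sequence) and 0.25 for the reduced profile, preserving that relative
  extent at its coarser depth sampling. The geometry is drawn from the patient's
  seed alone, so the ground-truth lesion mask can be reconstructed in
  stack space (`stack_lesion_mask()`) for localization statistics.
* Everything is a pure function of the configuration, including the seed;
  two calls produce byte-identical cohorts.

What the phantoms deliberately do **not** model: k-space/relaxometry
physics, partial-volume effects, motion or bias-field artifacts,
anatomical variability beyond ellipse jitter, or realistic sagittal/
coronal content (those slices only need correct plane tags, since the
pipeline discards them). Passing tests on phantoms therefore demonstrate
that the pipeline's machinery is correct and that the classifier can
learn a periventricular hyperintensity signal — not clinical performance.

## Problem sizes and numerical choices

The full `"paper"` profile is used for all architecture verification
(construction and counting only — no training). Training runs use the
`"reduced"` profile: `(24, 32, 32, 1)` stacks, slice totals in [9, 21],
matrix sizes {64, 256}, lesion radius 14 (on the 128-pixel reference
grid) and contrast 3 — a high-contrast, desk-scale cohort of 40 patients
(27 diseased : 13 control, the clinical ratio). Only three conv blocks
fit a 24×32×32 input (a fourth valid 3×3×3 convolution is impossible at
1×2×2), so the reduced architecture keeps blocks 1–3 and the identical
dense head (23,357 parameters). With the headline recipe (Adam,
rotation+affine augmentation, batch 4, 90 epochs) this cohort is learned
to ≥ 0.9 held-out accuracy, and the mean CAM relevance inside the true
lesion masks exceeds the mean outside — the package's synthetic analogue
of the source's reported behavior, which is not numerically reproducible
without the private cohort.

Other numerical details: ties in max pooling resolve to the first window
element (column-major scan); `sigmoid()` is computed in a branch-stable
form; constant-variance batch-norm channels are guarded by ε; the AUC of
a single-class sample is `NA`; phantom pixel intensities are integers
clipped to [0, 4095].

## Known limitations

* The engine is CPU-bound and single-threaded; the full profile is
  practical for construction and inference but slow to train — by design
  the package's claims about training are made at the reduced profile.
* Stacks are serialized with `saveRDS()`; no HDF5 container is used.
* The phantom's "sequences" differ only by stylized intensity profiles;
  no attempt is made to model real MR contrast.
* Precision is reported as the positive-predictive-value formula
  `TP/(TP+FP)`; the source text's gloss of precision as "specificity" is
  a misnomer its own formula contradicts, and the formula wins.
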