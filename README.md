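# voxcnn

Volumetric 3D-CNN screening of grade-1 cerebral small vessel disease
(cSVD) from brain MRI, end to end: raw per-patient DICOM slice series →
fixed-shape normalized stacks → a compact 3D convolutional classifier →
augmented, cross-validated training with confusion-matrix/ROC metrics →
Grad-CAM saliency volumes that localize the evidence.

**Who it is for.** Researchers studying automated WMH/cSVD grading who
need a reproducible, dependency-light reference pipeline, and method
developers who need a fully testable stand-in for private clinical MRI:
the package ships a seeded phantom-cohort generator that writes standard
DICOM series (mixed T1W/T2W/FLAIR sequences, mixed 64/256/512 matrices,
scout slices, multiple planes) with hyperintense periventricular lesions
injected into the diseased class, so every stage runs without any
clinical data.

## The model

Each patient's axial T1W/T2W/FLAIR slices are instance-sorted, filtered,
area-downsampled to 128×128, z-scored with pooled cohort statistics
(x̂ = (x − μ)/σ), and zero-padded along depth to a fixed stack of shape
(120, 128, 128, 1). The classifier is four Conv3D–BatchNorm–MaxPool
blocks (3×3×3 kernels, stride 1, valid padding, ELU; 8/16/32/64 filters;
2×2×2 pooling) followed by dense(40)–dropout(0.2)–dense(10)–dropout(0.2)–
dense(1, sigmoid), with He initialization and L2 = 0.05 on every conv and
dense weight — 534,653 parameters (534,413 trainable). Training minimizes
binary cross-entropy + L2 with Adam (LR 0.001, reduce-on-plateau), after
class-balancing augmentation (translation / shear / rotation / affine,
applied slice-wise in-plane). AUC is the rank statistic with ties counted
½; precision/recall with empty denominators are reported `NA`. Grad-CAM
weights a deep conv block's feature maps (block 4, 5×6×6×64, on the full
profile) by the spatially averaged logit gradient, rectifies, upsamples
trilinearly and max-normalizes.

There is no deep-learning runtime dependency: the forward and backward
passes (including batch-norm and Adam) are implemented in the package,
with compiled Rcpp kernels for 3D convolution and pooling, and are
verified against sliding-window oracles and finite differences.

## Worked example

```r
library(voxcnn)

# the classifier, as data
print_model_table(architecture("paper"))
#  layer            input_shape               output_shape             parameters
#  Input            (None, 120, 128, 128, 1)  (None, 120, 128, 128, 1) 0
#  Conv Block1      (None, 120, 128, 128, 1)  (None, 59, 63, 63, 8)    256
#  Conv Block2      (None, 59, 63, 63, 8)     (None, 28, 30, 30, 16)   3,536
#  Conv Block3      (None, 28, 30, 30, 16)    (None, 13, 14, 14, 32)   13,984
#  Conv Block4      (None, 13, 14, 14, 32)    (None, 5, 6, 6, 64)      55,616
#  Flatten          (None, 5, 6, 6, 64)       (None, 11520)            0
#  Fully Connected  (None, 11520)             (None, 40)               460,840
#  Dropout          (None, 40)                (None, 40)               0
#  Fully Connected  (None, 40)                (None, 10)               410
#  Dropout          (None, 10)                (None, 10)               0
#  Fully Connected  (None, 10)                (None, 1)                11
#  Total Parameters                                                    534,653
#  Trainable Parameters                                                534,413
#  Non-Trainable Parameters                                            240

# a synthetic cohort on disk, preprocessed into stacks
cfg <- phantom_config(n_diseased = 2, n_control = 1,
                      slice_count_range = c(23, 115), seed = 7)
man <- write_cohort(cfg, "cohort")
man
# # A tibble: 3 × 4
#   patient_id label    patient_seed n_axial
# 1 P001       diseased        70150      75
# 2 P002       diseased        70251     103
# 3 P003       control         70352      67

stats <- compute_dataset_stats(prepare_slices(load_series("cohort/P001")))
stack <- build_stack("cohort/P001", stats)
stack
# <volume_stack 120x128x128x1  patient=P001  label=NA  real slices=75>
```

`n_axial` is the number of diagnostic (≥128-pixel) axial slices; the
stack pads those 75 slices with 45 zero slices to the fixed depth of 120.
A full desk-scale run — phantoms, preprocessing, augmented training on
the reduced (24, 32, 32, 1) profile, held-out evaluation, CAM overlays —
is one call:

```r
run <- run_pipeline(run_config(profile = "reduced", epochs = 90,
                               output_dir = "run1", seed = 1))
run$metrics   # held-out accuracy/auc/precision/recall/bce_loss
```

A thin CLI over the same functions lives at `inst/cli/voxcnn`
(subcommands `phantom`, `preprocess`, `summary`, `train`, `explain`,
`run`).

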