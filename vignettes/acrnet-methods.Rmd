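---
title: "Segmenting osteosarcoma MRI slices with ACRNet: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting osteosarcoma MRI slices with ACRNet: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omsas)
```

## The problem

Osteosarcoma is a malignant bone tumor whose MRI appearance is highly
variable: lesion shape, position and texture differ between patients, and
scanner or contrast-agent differences shift global image brightness from
acquisition to acquisition. The package implements a complete pipeline for
delineating the tumor region in independent 2-D grayscale MRI slices as a
binary mask, built around ACRNet — a lightweight encoder–decoder
convolutional network that combines depthwise-separable residual blocks
with *attention condensers*, a squeeze-excite-style channel attention unit
computed on a spatially condensed embedding.

Everything here runs on synthetic limb phantoms, so each stage is testable
without clinical data; the section on the generator explains what the
phantoms do and do not emulate.

## Preprocessing

Raw slices pass through four steps before reaching the network.

1. **Binarization.** A pixel maps to foreground when its intensity exceeds
   the mean intensity of the whole image. The sign-based rule is undefined
   for pixels exactly at the mean; `omsas` sends ties to foreground
   (`tie_to_foreground = TRUE`), which keeps uniform regions inside the
   retained area rather than failing on a 0/0.
2. **Hole filling.** Background regions not 4-connected to the image
   border are enclosed holes and become foreground, leaving an image of
   pure black and pure white regions. The connectivity (4 rather than 8)
   is a package choice; the flood fill starts from the border so open
   notches survive.
3. **Effective-region cropping.** The smallest rectangle containing every
   white pixel becomes the crop box, and the box is applied to *both* the
   slice and its label mask — cropping only the image would misalign the
   pair. We use the box of all white pixels rather than the largest
   component only: simpler, and it can never exclude tissue. Boxes are
   1-based and inclusive, following R indexing convention.
4. **Min–max normalization.** `(p - p_min) / (p_max - p_min)` maps each
   image exactly onto [0, 1], removing the per-acquisition brightness
   offsets. A constant image has no range; it maps to
   `constant_image_value` (default 0). The transform is idempotent.

The image is then resized bilinearly to the network input size (default
256×256; the probe configurations use 64×64), the mask with
nearest-neighbor so it stays strictly binary.

## Dihedral augmentation

Training data are expanded by the full symmetry group of the square: the
four rotations and their horizontally flipped copies, 8 distinct images
per input. The naive recipe "originals + three rotations, then horizontal
and vertical flips of each" generates 12 images containing duplicates;
emitting the 8 unique dihedral-orbit elements makes the advertised
eightfold expansion hold exactly. A seeded random quarter of the augmented
images (by default) receives additive Gaussian noise with sd 0.05 of the
normalized range, clipped back to [0, 1]; the noise model and magnitude
are package choices, labels are never perturbed, and inference inputs are
never noised.

## The network

`build_acrnet()` assembles, from an `acrnet_config()`:

* a **stem** reservation block (1×1 convolution + layer normalization +
  ReLU) lifting the grayscale input to the first stage width;
* per encoder stage, `units_per_stage` **residual units** — two
  depthwise-separable ("retracting": depthwise 3×3 then pointwise 1×1)
  blocks with layer normalization, skip-added to the unit input before the
  final ReLU — followed by one **attention condenser**, then 2× max-pool
  and a reservation block into the next stage width;
* a mirrored **decoder**: nearest-neighbor upsampling, concatenation with
  the stage's encoder output, a reservation block to merge channels, and
  the same residual units;
* a 1×1 convolution **head** with a sigmoid producing per-pixel tumor
  probabilities.

The **attention condenser** condenses its input (2× spatial max-pool and a
pointwise reduction to `floor(c / ratio)` channels), embeds the activation
pattern with one depthwise-separable convolution, expands back to `c`
channels, upsamples, and squashes through a sigmoid into per-pixel,
per-channel gates in (0, 1) that multiply the input. Because gates are
strictly below 1, attention only attenuates — it never amplifies. `ratio`
trades embedding capacity against parameters; doubling it strictly shrinks
the block.

The channel-attention arithmetic is also exposed directly:
`channel_squeeze()` (spatial mean per channel), `channel_excite()`
(`sigmoid(W_rho · relu(W_sigma · z))`) and `apply_attention()`. The
wording that inspired the excite step is ambiguous about which
nonlinearity sits inside; we use the standard squeeze-excite ordering,
inner ReLU and outer sigmoid.

Layer normalization here normalizes across channels at each spatial
position with a learned per-channel affine — the stable choice for
convolutional features when batches are small.

Where published materials do not pin down stage widths, depth or condenser
placement, the default configuration is an explicit reconstruction choice:
4 stages of widths 32/64/128/256 with 2 residual units per stage and
`ratio = 4`. It instantiates at about 0.63 M trainable parameters —
comfortably inside the ≤ 6.91 M budget the architecture family targets.
`count_parameters()` agrees with a closed-form per-block audit for any
configuration (tested).

Weight initialization is He-uniform for convolutions, ones/zeros for the
normalization affine, all from the configuration seed; forward passes are
deterministic given weights and input. The depthwise convolution, layer
normalization and pooling kernels are implemented in C++ (src/) with exact
hand-derived backward passes; the full network gradient is verified
against central finite differences in the test suite.

## Training

The loss is the Tversky loss `1 − T(α, β)` with

`T = ΣRQ / (ΣRQ + α ΣR(1−Q) + β ΣQ(1−R) + ε)`,

R the predicted probabilities, Q the binary truth, and defaults α = 0.25,
β = 0.75, ε = 1e-8. β > α penalizes false negatives more than false
positives, pushing training toward high recall — in tumor detection a miss
is costlier than a false alarm. At α = β = 0.5 the index reduces exactly
to the Dice coefficient (the stabilizer ε is the only deviation, which is
why the identity test uses a vanishing ε). The index is defined as T
itself, i.e. 1 for a perfect prediction; the minimizable loss is 1 − T.

The optimizer is Adam at learning rate 1e-4 — the optimizer family is a
package choice (none is pinned by the architecture description); Adam is
standard for medical segmentation and stable under Tversky loss. Batch
size defaults to 8 and is configurable; the learning probes use batch
size 1 because Adam's per-parameter step is bounded by roughly the
learning rate, so at a fixed small epoch budget more (smaller) steps move
the network further. Epochs default to 460 with best-checkpoint selection
by validation DSC; whether a run of that length would benefit from early
stopping is left to the user, who can simply lower `epochs`.

Splits are **patient-level**: `split_patients()` shuffles patient ids with
a seeded RNG and assigns `round(0.7 · n)` to training (210 patients →
147/63), so no patient contributes slices to both sides;
`kfold_patients()` produces balanced folds (sizes differing by at most 1)
for 10-fold cross-validation.

## Inference: compound decision

`predict_compound()` predicts on all 8 dihedral copies of a slice,
inverse-transforms each binary prediction back to the original frame, and
fuses them by per-pixel majority vote: tumor where at least half the
copies agree, with exact ties resolved *to* tumor, consistent with the
recall-first loss. Two auditability escapes exist: `mode = "mean"`
averages the probability maps before thresholding, and
`literal_eq6 = TRUE` applies the sign-based voting formula exactly as
printed in the source description of this fusion rule — that convention
returns 1 when the vote is *below* half, i.e. it inverts the majority, so
it is off by default. The fused prediction is equivariant: transforming
the input permutes the orbit, so the output transforms with it (tested
exhaustively over all 8 transforms).

`attention_overlay()` renders the channel-mean condenser gate of a chosen
encoder stage, bilinearly upsampled and blended as a heat layer over the
slice; brighter/warmer regions mark where that stage's attention
concentrates.

## Metrics

`metrics()` reports accuracy, precision, recall, F1, IoU and DSC from the
pixel confusion matrix with tumor as positive class. Two recalls are
emitted: `recall_paper` = TN/(TN+FN), the negative-class ratio printed in
the metric panel this package reproduces, and `recall_standard` =
TP/(TP+FN), the conventional sensitivity. The reported `f1` follows the
panel (harmonic mean of precision and `recall_paper`); `f1_standard` uses
the conventional recall. Degenerate 0/0 ratios score 1 when both masks are
empty (perfect agreement) and 0 when exactly one is empty. `dsc` and `iou`
satisfy `dsc = 2·iou/(1+iou)` identically. Dataset-level aggregation is
the unweighted mean of per-slice metrics (macro averaging). `sett()` is
the mean wall time of a training epoch — purely hardware-dependent, so it
is reported but never compared across machines.

## The phantom generator

`generate_phantom()` emulates the features of this task that the pipeline
must handle: a dark background; a bright elliptical "limb" cross-section
with smooth sinusoidal internal texture; one tumor blob whose boundary is
a circle modulated in polar angle by three random low-order harmonics
(`r(θ) = r0 (1 + a Σ w_k sin(kθ + φ_k))`, star-shaped hence 4-connected);
a per-image global brightness offset emulating scanner differences (what
min–max normalization removes); and a small sensor-noise floor. Presets:
`easy` (contrast +0.35, irregularity 0.15, jitter ±0.10) for learning
probes, `hard` (contrast +0.15, irregularity 0.40, jitter ±0.25) for
robustness tests. Values were chosen once as plausible for T2-like
bright-lesion slices, with intensities constructed to stay inside [0, 1]
so 8-bit PNG round-trips lose nothing but quantization.

What the phantoms deliberately do **not** emulate: true MR physics
(k-space sampling, coils, bias fields), anatomy beyond one limb-like
ellipse, multi-focal or infiltrative lesion geometry, and inter-slice 3-D
structure. Passing tests therefore demonstrate that the pipeline's
mechanics (preprocessing, group algebra, optimization, fusion, metrics)
are correct and that the network can learn a separable lesion — they say
nothing about clinical segmentation accuracy, which depends on real data
this package does not ship.

`generate_dataset()` mirrors a patient/slice file layout: slices of one
synthetic patient share limb and tumor geometry up to a small wobble, the
plane label cycles transverse/coronal/sagittal, and everything is
reproducible bit-for-bit from one seed.

## Numerical choices and scaled-down problem sizes

* Layer-norm stabilizer 1e-5; Tversky stabilizer 1e-8; Adam (0.9, 0.999,
  1e-8).
* Max-pool ties take the first maximum in a fixed candidate order, making
  forward and backward bit-reproducible.
* Majority-vote ties go to tumor; threshold ties (`p == 0.5`) go to tumor.
* All randomness (weights, shuffling, noise, phantom geometry) flows from
  explicit integer seeds; derived per-image seeds stay below 2^31.
* The test suite exercises training at deliberately small scale — a
  ~0.1 M-parameter, 3-stage network on 200 easy 64×64 phantoms for 10
  epochs, and micro-networks at 16–32 px for structural checks — sizes
  chosen so the whole suite runs on one CPU in minutes while still
  demonstrating real learning (held-out DSC ≥ 0.85 on easy phantoms).

## Known limitations

* Single 2-D slices only; no volumetric context, registration or
  bias-field correction.
* Binary output (tumor vs background), matching the task's binary gold
  standard.
* The published architecture's exact widths/depths are not recoverable;
  the default here is one faithful-in-spirit reconstruction, not a weight-
  level reproduction, and clinical-data scores from the source panel are
  not reproducible without that data.
* Training is CPU-oriented and single-threaded beyond BLAS; it is meant
  for moderate 2-D problems, not large-scale 3-D workloads.
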