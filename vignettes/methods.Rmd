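---
title: "Automated hepatic lesion detection for somatostatin-receptor PET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated hepatic lesion detection for somatostatin-receptor PET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dotapet)
```

## The problem

Hepatic metastases of neuroendocrine tumors are imaged with
somatostatin-receptor PET (⁶⁸Ga-DOTATATE), where the normal liver itself
shows high and variable tracer uptake and image noise is substantially
higher than in ¹⁸F-FDG PET (lower administered dose, faster decay). Lesion
detection is therefore a low-contrast, high-noise task, and manual
annotation of lesions is the bottleneck for building automated detectors.

`dotapet` implements the full loop of a semi-automated annotation and
deep-learning detection pipeline:

1. **phantom** — synthetic liver studies with known ground truth;
2. **annotate** — background-sphere statistics, a modified PERCIST
   threshold, 3D candidate detection and gradient-edge boundary refinement;
3. **unet / train** — a 2D residual U-Net with contextual aggregation
   layers, trained with a 6:1 binary cross-entropy + Dice objective by
   momentum SGD with early stopping;
4. **detect** — binarization of the per-pixel score map, in-slice connected
   components, pixel-area noise filtering;
5. **evaluate** — lesion-level IoU matching (strictly above 0.05),
   PPV/sensitivity/F1, precision–recall curves and replicate aggregation.

## The synthetic phantom

Real patient studies are not distributable, so every stage is exercised on
phantoms whose *statistical* structure mirrors the study population the
pipeline targets:

* per-study slice counts uniform in 23–71 trans-axial slices;
* abnormal studies carry `round(N(4, 2.75²))` lesions clamped to 1–9
  (an abnormal study has at least one lesion, and studies with ten or more
  well-defined lesions fall outside the inclusion rules);
* each lesion is a sphere spanning 4–5 consecutive slices, realized by the
  interplay of the sampled radius (8–10 mm by default), the slice thickness
  (pixel spacing × an anisotropy factor), and a half-slice jitter of the
  axial center; the rasterized extent is trimmed to the upper span bound;
* lesions are non-confluent by construction: centers are re-drawn until all
  sphere surfaces are separated by a safety margin, and a property test
  verifies that no two lesion ids touch under 26-connectivity;
* the liver is a per-slice ellipse (jittered center, tapered ends) filled
  with a uniform background activity; lesion uptake is
  `contrast × background`, with contrast uniform in 2–4 by default.

Activity maps are blurred in-plane with a Gaussian point-spread function
(FWHM 6 mm by default, a typical clinical PET resolution) and i.i.d.
Gaussian noise is then added and clipped at zero. Two choices deserve
justification:

* **Noise after blur.** The detection threshold below is defined through
  the standard deviation of background liver. Adding stationary Gaussian
  noise *after* the point-spread keeps that SD exactly the configured
  `noise_sigma`, so threshold semantics are transparent and testable; a
  blurred-noise model would attenuate the SD by an amount that depends on
  the blur kernel. Reconstruction-correlated noise is out of scope.
* **Ground truth = pre-blur extent.** Labels record the hard sphere before
  the point spread, giving a target that does not depend on the annotation
  stage or on the blur setting.

The in-plane-only blur reflects the grid anisotropy: with 4 mm pixels and
4 mm or thicker slices, cross-slice spill is second order for spheres that
span only 4–5 slices, and in-plane blur is what creates the non-trivial
gradient edge the annotation stage must find.

Defaults (`background_mean = 100`, `noise_sigma = 15`,
`contrast ∈ [2, 4]`) put lesions safely above the detection threshold
(`200 > 1.5·100 + 2·15 = 180`): detectability by construction, enforced by
the spec validator and switchable off (`ensure_detectable = FALSE`) to
study the sub-threshold regime. These three numbers are free parameters of
the phantom — chosen once as a plausible low-SNR regime — not measurements
of any patient population, and none of the package's correctness claims
depend on their exact values.

What the phantom deliberately does **not** model: attenuation, scatter and
reconstruction physics, respiratory motion, PET/CT misregistration,
heterogeneous liver backgrounds (cirrhosis, steatosis), and confluent
lesion clusters. Tests passing on phantoms therefore demonstrate the
*mechanics* of the pipeline — thresholding, edge refinement, learning,
matching, filtering — not clinical performance.

## Semi-automated annotation

The gold-standard workflow places three spheres (3 cm diameter) in normal
background liver, derives the modified PERCIST threshold

\[ T \;=\; 1.5\,\mu_{bg} \;+\; 2\,\sigma_{bg}, \]

detects candidate lesions as 26-connected components of supra-threshold
voxels inside the liver (strictly `> T`; the strict/non-strict choice is
unstated in the protocol and strict was fixed here), and refines each
candidate's boundary with a gradient-edge operator.

**Sphere placement** is automated and deterministic where the clinical
workflow relies on an operator: candidate centers are scanned on a fixed
grid, kept only if the whole sphere fits inside the (exclusion-free) liver,
and ranked by the activity variance inside the sphere computed on a lightly
smoothed copy of the image (σ = 1 px). Smoothing makes the statistic
sensitive to *structure* — lesions, organ edges — rather than to which
candidate happened to draw the smallest noise realization; the reported
mean and SD always come from the raw voxels of the three selected,
non-overlapping spheres. The SD is pooled over all sphere voxels (n−1
denominator); whether the clinical protocol pools or averages per-sphere
SDs is unstated, and pooling was fixed here. A property test confirms the
pooled SD tracks the generator's `noise_sigma` within 10%.

**Gradient-edge refinement** stands in for proprietary gradient-edge
delineation tools, as a documented, replaceable strategy: on each slice a
candidate touches, rays are cast from the in-slice peak voxel (32 by
default); along each ray the boundary is placed at the maximum-magnitude
intensity gradient (central differences on a 0.1 px bilinear profile),
searched between the peak and just past the first crossing below the
background level; the refined mask is the region enclosed by the per-ray
radii, interpolated linearly across ray angles, and always contains the
peak voxel. On an unblurred disk the maximum gradient sits on the
step itself, so the refined mask reproduces the rasterized disk exactly —
an acceptance property of the suite. Single-voxel candidates are returned
unchanged with a warning record. The physician accept/modify/delete review
is represented by an audit log, not an interactive editor.

## The network

The detector is a 2D fully convolutional residual U-Net applied
independently to each liver-masked, per-study max-normalized slice:

* encoder: four residual blocks (3×3 convolutions, batch norm, ReLU,
  identity or 1×1-projection shortcut) joined by stride-2 convolutions,
  channel widths `C, 2C, 4C, 8C` with a `16C` bridge (`C = 32` by default;
  the scaled-down studies in this package use `C = 8`);
* decoder: four residual blocks joined by stride-2 transposed
  convolutions; each encoder block's *output* is concatenated to the
  corresponding decoder block's *output* (four long-range skips);
* two contextual aggregation branches return the two deepest decoder-level
  feature maps (at 1/8 and 1/4 resolution, after their skips) to full
  resolution through stride-8 and stride-4 transposed convolutions;
* fusion is channel concatenation of the decoder head with both aggregation
  branches, followed by a single 1×1 convolution and a sigmoid to a
  one-channel score map in [0, 1].

Unstated architectural details were fixed as: 3×3 kernels, batch
normalization, ReLU, transposed-convolution kernel size equal to its stride
(non-overlapping upsampling), and concatenation + 1×1 convolution for the
"fusion" step. The exact source layers of the aggregation branches are
ambiguous in the source description; the two deepest post-skip decoder
maps were chosen so that the stride-4/stride-8 factors match their
resolutions. All of this is confined to `model_config()` /
`build_model()`.

Inputs whose spatial size is not divisible by 16 are reflect-padded to the
next multiple and the output cropped back. Inference uses batch-norm
running statistics and is deterministic; slices are independent entities,
so permuting slices permutes predictions.

The forward/backward passes are implemented in the package itself (R
orchestration over im2col/GEMM convolution kernels in C++), with exact
gradients: the suite finite-difference-checks the whole network and the
loss, which is

\[ L = 6\,\mathrm{BCE}(p, t) + \mathrm{Dice}(p, t), \qquad
   \mathrm{Dice} = 1 - \frac{2\sum p t + \varepsilon}
   {\sum p + \sum t + \varepsilon}, \]

with `ε = 1e-6` (so the empty-prediction/empty-target case is 0) and BCE
clipping scores to `[1e-7, 1 − 1e-7]`. The 6:1 ratio is applied as raw
multipliers. No class-imbalance machinery beyond the Dice term is used,
and training batches are drawn uniformly over slices.

## Training protocol

Momentum SGD (`lr = 0.01`, `momentum = 0.9`, polynomial decay
`lr·(1−it/max)^0.9` — learning-rate details are not fixed by the source
protocol and are exposed in `train_config()`), with paired augmentation of
image and label (horizontal flip p = 0.5, rotation ±10°, translation ±5%;
nearest-neighbor resampling keeps labels binary). The full-scale protocol
is 100 000 mini-batch iterations with early stopping after 20 000
iterations without validation improvement; "iterations" are taken to be
mini-batches. The validation metric — unspecified beyond "performance on
the validation set" — is the lesion-level F1 at the default detection
settings (binarization 0.05, 5 px filter), matching the headline metric.
The best-validation checkpoint is restored at the end, and the whole
train/validate/test cycle is repeated over independent replicate seeds
(five at full scale) for mean ± SD reporting.

## Detection and evaluation

Prediction maps are binarized strictly above a score threshold (0.05
default), labeled into in-slice 8-connected components, and filtered by
pixel area: components with area *below* the filter are removed, so a
component exactly at the filter size survives. Components are 2D because
the network treats each slice as a discrete entity and filters are quoted
in pixels; candidate *annotation* components are 3D/26-connected because
gold lesions are volumetric.

Matching is greedy one-to-one by descending IoU with strict acceptance
(`IoU > 0.05`). Predictions (2D, per-slice) are matched against the
per-slice footprints of each gold lesion. This granularity is the one
consistent with reporting high PPV together with multi-slice lesions — a
correct single-slice detection of a five-slice lesion is one true positive
against that slice's footprint, and a spurious detection on the adjacent
slice is a false positive — and it reproduces the characteristic
adjacent-slice error modes of slice-wise detectors. For evaluating the 3D
annotation stage the same matcher runs on whole-lesion voxel sets.

PPV, sensitivity and F1 pool true/false positives over all test studies
(micro-average; a per-study average mode exists as an option). The 0/0
conventions: when there is nothing to find and nothing predicted all three
metrics are 1, otherwise an undefined ratio is 0. Precision–recall curves
sweep the binarization threshold over a fixed score grid with the area
filter held fixed; the AUC is trapezoidal over recall, anchored at recall
0 with the first point's precision and truncated at the largest observed
recall (no optimistic extrapolation to recall 1). Replicate aggregation
reports mean and n−1 SD per (metric, filter) cell; because the mean of
per-replicate F1 values need not equal the F1 of the mean PPV and mean
sensitivity, both are reported (`f1` and `f1_of_means`).

## Numerical and degenerate-input choices

* `percist_threshold()` is exact arithmetic; property-tested over random
  (μ, σ).
* Component labels are assigned in first-pixel scan order (rows, columns,
  slices), so labelings are deterministic.
* Greedy matching breaks IoU ties by (prediction id, gold id).
* Empty candidate sets, all-background studies, and single-voxel
  components are all legal inputs with defined behavior.
* Training aborts with a diagnostic on non-finite loss; splits must be
  non-empty; infeasible stratified splits error rather than truncate.
* PET intensities written to 8-bit PNG round-trip within half a
  quantization step of the sidecar window; masks round-trip exactly.

## Problem sizes used by the shipped studies

The packaged tests and the acceptance script exercise the pipeline end to
end at a reduced size chosen for a single CPU: 40 studies of 64×64 px
(4 mm pixels) with 23–27 slices each (18 abnormal, 22 normal), a 60/20/20
stratified split, two replicate networks with `base_channels = 8`, batch
size 4, and 1200 training iterations with validation every 150 and
patience 900. Under these conditions the held-out lesion-level F1 at the
best pixel filter exceeds 0.7 and sensitivity falls monotonically with
filter size, reproducing the qualitative filter-sweep trend at full scale.
The full-scale protocol (100k iterations, five replicates, `C = 32`)
is available through the same configuration objects.

## Known limitations

* The phantom's Gaussian noise and hard-sphere lesions are idealizations;
  no claim is made about clinical metric values, only about pipeline
  mechanics and trends.
* The gradient-edge operator is a documented stand-in for undisclosed
  commercial delineation algorithms; its agreement with any particular
  tool is untested.
* The CNN engine is CPU-only and sized for small studies; it is not a
  general deep-learning framework.
* 2D slice independence is inherent to the design: lesions are never
  aggregated across slices at detection time, and cross-slice context is
  known to be the dominant error source of slice-wise detectors.
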