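---
title: "Dual-decoder nuclei instance segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-decoder nuclei instance segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem and the model

Nuclei instance segmentation in hematoxylin & eosin (H&E) stained histology
must do two things at once: decide which pixels are nucleus (semantic
segmentation) and split the nucleus foreground into individual objects,
including nuclei that touch or partially overlap. `nucseg` addresses this
with a multi-task encoder–decoder network: one U-Net encoder feeds **two
decoders**,

* a **foreground decoder** ending in a 1-channel sigmoid head, trained
  against *refined* binary masks (touching borders removed, 1-px erosion),
  with soft Dice loss plus binary cross-entropy;
* a **distance decoder** ending in a 1-channel linear head regressing a
  per-nucleus normalized Euclidean distance map, with mean squared error.

The three loss terms are summed with equal weights. The two output maps are
merged deterministically: threshold the foreground, estimate the mean
nucleus area, smooth the distance prediction with a Gaussian whose sigma is
proportional to the equivalent nucleus radius, seed at its local maxima and
flood a marker-controlled watershed on the negated smoothed map, then remove
objects under 30 px and fill enclosed holes. Nucleus *classification* is a
separate single-decoder U-Net with a `(K+1)`-channel softmax head
(background plus K classes); detected instances take the modal pixel class
(majority vote, ties toward the lowest class index).

The encoder has five convolution blocks by default (two 3×3 convolutions
with ReLU and a dropout layer at rate 0.1 between them, then 2×2 max
pooling), so valid input sides are multiples of 32; arbitrary images are
white-padded to a square and resized to the nearest multiple of 32, and the
inverse mapping is applied to the predicted label mask. Training uses Adam
at an initial learning rate of 0.001, dropped by a factor of 0.1 every 20
epochs, for 120 epochs, from Xavier-initialized weights; there is no early
stopping — the last epoch's weights are the model. Test-time augmentation
averages predictions over {identity, 90° rotation, horizontal flip}, and
cross-validation fold models can be ensembled by elementwise averaging.

All of the network arithmetic — im2col convolutions, transposed-convolution
upsampling, pooling, dropout, the analytic backward pass and Adam — is
implemented in base R on top of BLAS matrix products, with the two hot
gather/scatter kernels (im2col and its adjoint) and the watershed flood in
compiled code. Gradient correctness is pinned by finite-difference checks in
the test suite rather than taken on faith.

## Ground-truth preparation

Two training targets are derived from an instance label mask:

* **Refined binary mask** — every pixel whose 8-neighborhood contains a
  different nonzero label is set to background (so diagonally touching
  nuclei are also separated; without this, watershed regions can merge),
  then a binary erosion with a discrete disk of radius 1 (the 4-neighbor
  cross) is applied. An instance may vanish entirely; that is allowed and
  warned about. Border removal is idempotent, and no two source instances
  remain 8-connected afterwards.
* **Distance map** — per instance *independently*, the Euclidean distance
  of each instance pixel to the nearest non-instance pixel, divided by the
  instance maximum so every instance peaks at exactly 1 (single-pixel
  instances get 1). Normalization is per-instance rather than global: it
  makes the regression target scale-invariant across nucleus sizes, so the
  seed detector sees comparable peak heights for small and large nuclei.
  Distance maps are computed from the *original* labels, before erosion,
  so peaks stay centred on full nuclei. The published description of this
  target is terse; Euclidean distance with per-instance normalization is
  this package's reading, and both choices are isolated behind
  `make_distance_map()`.

One detail worth recording: the discrete erosion of the radius-5 digital
disk (81 px) by the radius-1 disk has area 53, not the area of the radius-4
digital disk (49) — erosion of digital disks does not commute with shrinking
the radius. The tests pin the brute-force value.

Augmentation applies flips and scaling identically to the image and all
targets (nearest-neighbor for targets, bilinear for the image; padding
introduced by down-scaling is white in the image and background in the
targets) and contrast/brightness to the image only. With flips only,
augmenting the targets equals rebuilding the targets from augmented labels
exactly; with scaling the two routes differ at instance borders, and the
package resamples the prepared targets (order-0) rather than regenerating
them, which keeps augmentation cheap and deterministic.

## The synthetic fixture generator

Real benchmark datasets cannot be bundled, so every stage is exercised on
synthetic H&E-like patches: rotated ellipses (semi-major radius and
eccentricity drawn uniformly from configured ranges, integer pixel centers
so discrete geometry is exact) rendered dark purple over a pink background
with a smooth radial falloff and additive Gaussian noise
(`noise_sd = 0.03` by default, roughly the photon/stain noise level of an
8-bit scanner patch). Overlaps are optional and bounded by a pairwise
overlap fraction; contested pixels go to the later-drawn nucleus so the
label mask is always a partition, and a placement that would disconnect or
erase an earlier nucleus is retried. Labels are draw order — no relabeling
by size — so regeneration under a fixed seed is bit-identical. Optional
per-nucleus classes are drawn from configurable proportions, with slight
color tints per class.

What the generator does *not* emulate: stain variability and deconvolution,
texture inside nuclei and stroma, imaging artifacts, and the heavy-tailed
shape variation of real nuclei. Passing the end-to-end tests therefore
shows the pipeline's machinery is correct and trainable, not that the small
preset would reach published benchmark scores on real tissue.

## Merge-stage numerics

The merge has a handful of constants, all exposed in `merge_config()`:

* `binary_threshold = 0.5` on the sigmoid head (the source work does not
  state one; 0.5 is the natural operating point of a calibrated head).
* `sigma_scale = 0.5`: Gaussian sigma = 0.5 × `sqrt(avg_area / pi)` (the
  equivalent radius of the mean nucleus), kernel truncated at 4 sigma,
  reflective boundaries. Smoothing proportional to object scale suppresses
  spurious maxima without merging adjacent peaks; the published sentence
  describing the kernel size is garbled, so the proportional rule is fixed
  here and config-exposed.
* `min_seed_distance_scale = 1.0` equivalent radii between seeds, and a
  peak floor of 10% of the map maximum, rejecting noise maxima.
  Tie-breaking is deterministic (value, then row, then column).
* Watershed floods the negated smoothed map from the seeds, restricted to
  the thresholded foreground, 4-connected, FIFO tie-breaking in the
  priority queue; foreground components without any seed get a fresh label
  each (the area filter removes debris later) so no detected tissue is
  silently dropped.
* `min_instance_area = 30` px and per-instance hole filling, applied in
  that order; the refinement is idempotent. `fallback_area = 100` px is
  used when the thresholded foreground is empty (flagged in the return
  value).

Degenerate inputs are defined, not accidental: empty foregrounds produce
zero seeds and an empty labeling; a constant map has no maxima above the
floor; instances of one pixel get distance 1; empty-vs-empty metric
comparisons score 1.

## Evaluation indices

`dice_score()`, `aji()` and `pq()` implement the standard indices. Two
ambiguities in the AJI literature are pinned for reproducibility: ground
truth instances are processed in ascending id, and ties in best-IoU choose
the lowest predicted id (order can change the score on pathological ties).
PQ matches pairs with IoU **strictly** above 0.5, where matching is
provably unique; the greedy matching is verified against a brute-force
optimal-assignment oracle on hundreds of randomized masks in the tests, and
`pq = sq × dq` holds exactly. Per-class average PQ restricts both masks to
one class at a time, so a correctly segmented instance with the wrong class
counts as a false positive for its predicted class and a false negative for
its true one; the mean is unweighted over classes present in the ground
truth. Metrics are reported per image and averaged without weighting —
whether the published tables pool differently is not stated, and this
choice is flagged here.

## Training protocol utilities

`make_cv_folds()` reproduces both protocols: leave-organs-out grouped folds
(groups shuffled under the seed, distributed round-robin, so a 30-sample /
10-organ dataset gives 10 folds of exactly 3 same-organ test images) and
seeded random k-fold (665 samples at k = 5 give test sets of 133).
`sample_class_balanced_patches()` instantiates the qualitative
"more patches from underrepresented classes" rule as inverse-frequency
weighting: each nucleus is drawn with probability proportional to
1/(global count of its class), patches are centered on the sampled nucleus
and shifted inside the image near borders. With the published class counts
(21,752 / 23,460 / 803 / 894) the two rare classes receive ~27× the
per-nucleus sampling weight of the common ones.

Batch size defaults to 4 (unstated in the source work; a free parameter
documented as such). Adam's β₁/β₂/ε are the framework defaults and are
recorded in the fitted model for provenance. Every random element —
initialization, shuffling, augmentation, dropout, patch draws — is derived
from explicit seeds, and the caller's RNG state is restored.

## Problem sizes used by the tests and the acceptance script

The bundled checks run entirely on synthetic data at sizes chosen for a
single CPU: metric oracles on 36×36 masks (200 randomized cases);
ground-truth properties on 96×96 fixtures (100 cases); the merge oracle on
twenty 256×256 patches with 12 nuclei of radius 8–14 px spaced ≥ 2.5 max
radii apart (ground-truth maps standing in for network outputs — detection
quality is expected near 1, matched IoU near 0.84, bounded by the 1-px
erosion of the binary target); and a 30-epoch smoke training of the small
preset (depth 3, 8 base filters) on sixteen 128×128 patches with four held
out. The small preset exists because the full 5-level/64-filter model is a
GPU-scale object; the architecture code is identical, only depth and width
shrink. The smoke-trained model reaches AJI ≈ 0.78 on held-out synthetic
patches versus 0.0 for an untrained network — far above the ≥ 0.30 / ≤ 0.05
property bounds the tests assert — but again, synthetic patches are an easy
domain; these numbers say the trainer, losses and merge work, not that the
preset generalizes.

## Known limitations

* The R implementation trains desk-scale models; the full-size published
  configuration (120 epochs, 512×512 images, 64→1024 filters, 5–10 fold
  ensembles) is expressible but not practical on one CPU.
* Overlap-aware (non-partition) instance representations are out of scope;
  ground truth and predictions are label partitions.
* Stain normalization/deconvolution, elastic deformation and HED-space
  color augmentation are not implemented.
* The classifier learns from whatever signal the data carries; on the
  synthetic fixtures, class tints are deliberately weak, so classification
  accuracy on fixtures mainly exercises the voting/evaluation path, which
  is tested with constructed probability maps instead.
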