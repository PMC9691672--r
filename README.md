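# nucseg

Nuclei instance segmentation and classification for H&E-stained histological
image patches, built around a **dual-decoder U-Net**: a shared encoder feeds
one decoder that predicts nuclei foreground (sigmoid head, soft Dice +
binary cross-entropy loss) and a second that regresses per-nucleus
normalized Euclidean distance maps (linear head, mean squared error), the
three losses summed with equal weight. The two output maps are merged into
instance labels by size-adaptive Gaussian smoothing, local-maxima seeding
and a marker-controlled watershed, followed by removal of objects under
30 px and hole filling. An independent single-decoder U-Net with a softmax
head classifies nuclei; each detected instance takes the majority pixel
class. Evaluation uses the field's standard indices — Dice, the aggregated
Jaccard index (AJI), and panoptic quality (PQ = SQ × DQ under strict
IoU > 0.5 matching) — and a synthetic H&E-like fixture generator makes the
whole pipeline runnable and testable without any external dataset.

Who it is for: image-analysis researchers who want a fully inspectable,
dependency-light R implementation of the distance-map + watershed family of
nuclei segmentation methods — every layer of the network, its analytic
backward pass, the Adam optimizer and the watershed flood are package code
(base R over BLAS, with the im2col kernels and the flood in C++), not calls
into a deep-learning framework.

## Worked example

Generate a synthetic patch, build its training targets, and run the merge
stage with the ground-truth maps standing in for network output — the
cleanest way to see the watershed reconstruction in isolation:

```r
library(nucseg)

cfg <- fixture_config(height = 128, width = 128, n_nuclei = 10,
                      radius_range = c(8, 14), seed = 7)
s <- generate_nuclei_image(cfg)     # image + instance labels (+ classes)
d <- make_distance_map(s$labels)    # per-nucleus distance, peaks at 1
b <- refine_binary_mask(s$labels)   # border-removed, 1-px eroded foreground
lab <- merge_outputs(d, b)          # smooth -> seed -> watershed -> refine
evaluate_instances(s$labels, lab)
#>       dice       aji        pq        sq dq
#> 1 0.916621 0.8460759 0.8400845 0.8400845  1
```

Every nucleus is detected (DQ = 1); the matched IoU of 0.84 is the expected
cost of the 1-px erosion in the binary training target, not a watershed
error. Training the small preset end to end:

```r
net <- build_dual_decoder(network_config(preset = "small"), seed = 7)
net
#> <nucseg_net> dual model, depth 3, base filters 8, 168,042 parameters

ds    <- generate_dataset(20, fixture_config(height = 128, width = 128,
                          n_nuclei = 10, radius_range = c(8, 14)), seed = 100)
train <- lapply(ds$samples[1:16], function(s) prepare_sample(s$image, s$labels))
model <- train_network(net, train, train_config(epochs = 30, batch_size = 4,
                                                seed = 1))
pred  <- predict(model, ds$samples[[17]]$image, type = "instances")
```

A 30-epoch run of this configuration takes a few minutes on one CPU and
reaches mean Dice ≈ 0.88, AJI ≈ 0.78, PQ ≈ 0.77 on held-out synthetic
patches (an untrained network scores AJI 0.0). `run_pipeline()` chains
fixtures → preparation → training → segmentation → evaluation from a single
(YAML-able) config with stage caching, and
`inst/scripts/nucseg.R` is a thin shell wrapper around it. The full-size
published configuration (depth 5, 64 base filters, 120 epochs, fold
ensembles, TTA) is expressible through the same API — `network_config()`,
`train_config()`, `ensemble_predict()`, `predict_with_tta()` — but is a
GPU-scale computation.

## Layout

- `R/` — fixtures, ground-truth preparation, network + losses + backprop,
  training utilities, post-processing/merge, metrics, pipeline.
- `src/` — im2col/col2im kernels, watershed flood, connected components.
- `vignettes/nuclei-segmentation.Rmd` — the model, its numerical choices,
  what the synthetic fixtures do and do not show.
- `tests/testthat/` — unit, property and end-to-end tests (all fixtures
  generated in code).
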