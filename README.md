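# semgraphics

Semantic-graphics learning for crop-row and weed detection in paddy fields.

## The problem

Autonomous weeding in row-transplanted rice needs two visual capabilities:
detecting the (possibly weed-obscured) **crop rows** that guide a robot
between rows, and telling **rice from wild millet** — a grass weed so
similar to rice that dense per-pixel annotation is impractical — for
in-row weeding.  *Semantic graphics* sidestep dense labelling: a human
sketches what matters (a few-pixel-thick polyline along each crop row; a
solid disc at each plant base, with larger radii nearer the camera), the
sketch is rasterized into a label mask, and a convolutional
encoder–decoder network is trained to reproduce it as a dense prediction.

This package implements that pipeline end to end in R, with the network
built from scratch on compiled im2col convolution kernels (no external
deep-learning framework):

* **Synthetic scenes** — a seeded generator of paddy-like images
  (perspective-converging rows of leafy green blobs, inter-row weed blobs
  of overlapping colour) with exact ground-truth graphics, standing in
  for field datasets that are not publicly distributable.
* **Annotation model** — polylines/keypoints, rasterization, JSON I/O,
  inverse-frequency class weights.
* **Extended-skip network (ESNet)** — VGG-style encoder, two large-kernel
  separable blocks at the encoder tail, learned multi-scale skip modules
  (a channel-preserving 1×1 path concatenated with a filter bank whose
  branches jointly add 12 channels: `C_in + 12` out), constant-width
  decoder.  All ablation variants (fixed UNet-style skips, single-scale
  skips, no large kernels) come from configuration alone.
* **Training** — class-weighted pixel-wise cross-entropy
  `L = -(1/N) Σ_i w_{y_i} log p(y_i)`, Adam, Xavier initialization,
  stepwise exponential decay `lr(t) = lr_0 · f^⌊t/T⌋`, seeded
  scale/rotation/mirror/photometric/crop augmentation.
* **Dominant-line extraction** — a simplified RANSAC: the longest
  connected segment seeds a least-squares line `x = a·y + b`, inliers
  within `d_thresh = 15` px (horizontal) are collected and the line refit;
  after the second iteration the line is final, its inliers and any
  segment >50 % covered are removed, and the next seed is processed.
* **Metrics** — per-class IoU `|T∩P| / |T∪P|` and mIoU,
  distance-thresholded keypoint precision/recall/F1 (`d_thresh = 15`),
  and mean pixel deviation (mpd): the mean over rows of `|x_pred − x_gt|`
  between matched lines.

## Worked example

```r
library(semgraphics)

spec  <- scene_spec(n_rows = 4, seed = 7)          # 512x512 synthetic paddy scene
scene <- generate_scene(spec)
scene$truth
#> <semantic_graphic> 512x512, 4 polyline(s), 56 keypoint(s) [paddy, millet]

mask <- rasterize_lines(scene$truth, thickness = 5)
round(compute_class_weights(mask, class_names = c("background", "line")), 3)
#> background       line
#>      0.516     15.813

res <- extract_dominant_lines(mask, n_lines = 4, d_thresh = 15)
res
#> <dominant_lines> 4 line(s)
#>   col = -0.2009 * row +  204.572   rows [101, 511], 2091 inliers
#>   col = +0.1996 * row +  307.103   rows [101, 511], 2081 inliers
#>   col = +0.0661 * row +  272.932   rows [101, 511], 2059 inliers
#>   col = -0.0674 * row +  238.757   rows [101, 511], 2058 inliers

mean_pixel_deviation(res$lines, scene$row_lines)$mpd
#> [1] 0.003457636

lr_schedule(c(0, 10000, 25000), base_lr = 1e-4,
            decay_factor = 0.94, decay_interval = 10000)
#> [1] 1.000e-04 9.400e-05 8.836e-05
```

The class weights show the ~31:1 background/line imbalance the weighting
corrects; the extractor recovers the four generating rows to ~0.003 px
because the mask is a clean rasterization of the ground truth — with a
trained network in the loop the deviation reflects prediction quality
instead.

Training and evaluation at desk scale:

```r
dataset <- lapply(semgraphics:::sg_child_seeds(11, 8), function(s) {
  sc <- generate_scene(scene_spec(image_height = 96, image_width = 96,
                                  n_rows = 4, row_spacing_at_bottom = 19,
                                  plant_spacing = 10, plant_radius_near = 4,
                                  plant_radius_far = 2, jitter_sd = 1, seed = s))
  list(image = sc$image, mask = rasterize_lines(sc$truth, 5), graphic = sc$truth)
})
net <- net_config(encoder_stages = list(c(2, 16), c(2, 32)),
                  tail_blocks = 2, tail_kernel = 7,
                  skip_mode = "multiscale", multiscale_kernels = c(3, 5, 7),
                  decoder_channels = 32, n_classes = 2)
fit <- train_model(build_model(net, seed = 1), dataset,
                   train_config(batch_size = 4, base_lr = 1e-3,
                                total_epochs = 20, seed = 1))
fit$best_miou
#> [1] 0.8572434
```

## Command line

```sh
semgraphics simulate --config run.json --n 100 --out scenes/
semgraphics train --config run.json --out run/
semgraphics predict --checkpoint run/checkpoint.rds --manifest scenes/manifest.tsv --out preds/
semgraphics extract-lines --mask preds/pred_0001.png --out lines.json
semgraphics evaluate --checkpoint run/checkpoint.rds --manifest scenes/manifest.tsv --task lines --out report.json
```

(the `semgraphics` script is installed under `inst/cli/`; equivalently call
`sg_main(c("simulate", ...))` from R).  The JSON config has sections
`scene`, `net`, `train`, `augmentation`, `paths` plus a top-level `seed`
that governs every source of randomness in a run.

## Layout

* `R/`, `src/` — implementation (graph-based network + Rcpp kernels,
  including a minimal PNG codec, since no pre-installed R PNG reader
  exists in the target toolchain)
* `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles
* `vignettes/semantic-graphics.Rmd` — methods notes: model assumptions,
  parameter choices, what the synthetic generator does and does not
  emulate
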