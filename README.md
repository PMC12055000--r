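# adpt — anti-drift animal pose estimation and identity tracking

Deep-learning pose estimators for freely behaving animals are prone to
*tracking drift*: a body-part estimate jumps to a visually similar but
wrong location (often with high confidence) or fails to be detected at
all. Both failure modes silently corrupt gait analysis, behaviour
classification and social-interaction statistics downstream. `adpt` is
an R implementation of an anti-drift pose-estimation pipeline for
behavioural researchers: a cascaded CNN–transformer keypoint network,
identity-aware decoding for multi-animal scenes, mix-up synthesis of
social training data, and a drift-centric evaluation suite — all
exercisable at desk scale through a deterministic synthetic scene
generator, with no external data or GPU required.

## The method

The network predicts four tensors at 1/8 of the input resolution:

- **confidence heatmaps** `H_k(c) = max_inst exp(−‖c − y_k/s‖² / 2σ²)`
  per keypoint *k* (stride *s*, width σ in map cells); the peak value is
  the detection confidence, and confidence ≤ 0.2 counts as a miss;
- **location refinement** — per-keypoint sub-stride offsets
  `(x − c_x·s, y − c_y·s)` recovering continuous coordinates from the
  coarse grid;
- **LRSS** (low-resolution semantic segmentation) — limb segments
  painted with instance identity, `M(p) = identity` if *p* lies on a
  limb, else 0; its channel masses classify single-animal identity via
  `argmax_id Σ_p p_id`;
- **BAF** (body affinity field) — on body pixels,
  `BAF(p) = p − center`; inverting it groups pixels by instance, and
  combining it with LRSS yields a per-pixel identity map used to assign
  identities to decoded peaks in social scenes.

A residual convolutional stem feeds three branches at 1/4, 1/8 and 1/16
scale; the 1/16 branch runs through a multi-head self-attention encoder
(learned 2-D positional embeddings) to capture long-range body
structure, and all branches are fused at 1/8 by skip connections.
Training uses AdamW under a warmup-cosine schedule (1e-5 → 1e-3 → 1e-5,
10 warm-up epochs, batch 8, weight decay 1e-4, 30-epoch early-stopping
patience) with RMSE losses on heatmaps / offsets / BAF and sparse
cross-entropy on LRSS.

Evaluation covers drift fraction (`‖y_i − y_{i−1}‖ > α`, α = 50 px for
mice, 30 px for monkeys), miss fraction (confidence ≤ 0.2), identity
change rate (center jumps > 75 px), PCK@0.15, OKS / AP@α / mAP
(thresholds 0.50–0.95, strict inequality), and RMSE with confidence
cutoffs. Temporal identity correction removes identity swaps by
motion-continuity assignment plus majority smoothing.

The forward and backward passes of the network are implemented from
scratch in Rcpp/RcppArmadillo (conv, deconv, layer-norm, multi-head
attention, AdamW) and validated against finite-difference gradients in
the test suite.

## Worked example

Encode a synthetic labelled scene into training targets, decode it
back, and measure drift on a synthetic video with one injected
100-pixel jump:

```r
library(adpt)
sk  <- toy_skeleton()                       # nose, back, tailroot, two paws
cfg <- adpt_config(sigma = 1.2)             # stride 8, sigma in map cells

fr  <- generate_scene(scene_spec(seed = 42))
tg  <- make_target_maps(fr, sk, cfg)
det <- decode_single(list(heatmap = tg$heatmap, locref = tg$locref), cfg)
cbind(round(det[, c("x", "y", "confidence")], 3), detected = det$detected)
#>        x      y confidence detected
#> 1 12.521 25.820      0.920     TRUE
#> 2 21.000 37.073      0.909     TRUE
#> 3 30.164 44.699      0.926     TRUE
#> 4 27.813 31.709      0.924     TRUE
#> 5 13.445 41.327      0.956     TRUE
```

The decoded coordinates equal the generator's ground truth to
sub-micro-pixel precision (peak cell + refinement offset). On a video,
the drift report localises an injected jump event exactly:

```r
vid <- generate_video(scene_spec(seed = 7, n_jumps = 1, jump_px = 100), 100)
vid$events$jumps
#>   frame animal keypoint       dx        dy
#> 1    12      1        4 89.12979 -45.34182
drift_report(vid$track, cfg, keypoint_names = sk$names)$per_keypoint
#>   keypoint drift miss
#> 1     nose  0.00    0
#> 2     back  0.00    0
#> 3 tailroot  0.00    0
#> 4    paw_l  0.02    0      # the jump: out and back = 2/100 frames
#> 5    paw_r  0.00    0
```

Training the `tiny` preset end-to-end (a few CPU-minutes):

```r
frames <- lapply(1:128, function(i) generate_scene(scene_spec(seed = i)))
cfg    <- adpt_config(sigma = 1.2, epochs = 150, monitor = "val")
model  <- build_model(model_spec("tiny", K = 5, input_size = c(64, 64)), seed = 1)
state  <- train(model, frames, cfg, seed = 1, skeleton = sk, augment_copies = 3)
heads  <- model_forward(model, frames[[1]]$image, cfg)
decode_single(heads, cfg)
```

A thin command-line front end (`inst/scripts/adpt`) wraps the same
functions: `adpt synth`, `adpt mixup`, `adpt train`, `adpt predict`,
`adpt evaluate`, `adpt convert`.

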