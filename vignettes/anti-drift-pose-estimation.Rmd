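---
title: "Anti-drift animal pose estimation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anti-drift animal pose estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adpt)
```

## The problem

Heatmap-based pose estimators for freely behaving animals suffer from
*tracking drift*: a keypoint estimate jumps to a visually similar but
wrong location (a cage corner, a cable, a second animal), often with
high confidence, or disappears altogether (a *miss*, low confidence).
Both failure modes corrupt downstream behaviour statistics. This
package implements a pose-estimation pipeline designed around that
failure mode — a convolutional-transformer network whose attention
layers capture long-range body structure, auxiliary training targets
that teach the network where the body is (not just where the keypoints
are), and an evaluation suite that quantifies drift directly.

## The model

The network maps an image to four tensors at 1/8 of the input
resolution ("head" resolution, `stride = 8`):

* **Confidence heatmaps** — one channel per keypoint $k$; the training
  target at map cell $c$ is
  $\max_{\text{instances}} \exp\!\big(-\lVert c - y_k/s \rVert^2 / 2\sigma^2\big)$
  with $s$ the stride and $\sigma$ the Gaussian width in map cells.
  The peak value doubles as the detection confidence; a prediction with
  confidence $\le 0.2$ counts as a failed detection.
* **Location refinement** — two channels per keypoint storing the
  sub-stride offset $(x - c_x s,\; y - c_y s)$ in image pixels,
  supervised within a radius of $2\sigma$ cells around each keypoint.
  Decoding adds the offset at the argmax cell, recovering continuous
  coordinates from the coarse grid.
* **Low-resolution semantic segmentation (LRSS)** — an integer label
  map that paints every limb segment (the thick rasterised line between
  the two endpoint keypoints of each skeleton edge) with the instance's
  identity label, 0 elsewhere. With $n$ identities the head has
  $n + 1$ softmax channels. LRSS serves two purposes: as an auxiliary
  loss it ties keypoints to body structure, and at inference its
  channel masses classify the identity of a single-animal frame
  ($\mathrm{identity} = \arg\max_{\text{id}} \sum_p p_{\text{id}}$).
* **Body affinity field (BAF)** — a two-channel vector field that, on
  every body pixel $p$ (the instance's LRSS footprint), stores
  $p - \mathrm{center}$ in map cells, where the center is a designated
  skeleton keypoint (the back, for a rodent). Inverting the field
  ($\hat c(p) = p - \mathrm{BAF}(p)$) groups body pixels by instance;
  reading the LRSS label at $\hat c(p)$ yields a per-pixel *identity
  map*. This is the bottom-up half of social decoding.

### Architecture

A convolutional stem produces 1/4-scale features (the full preset uses
a 7×7 stride-2 convolution followed by a stride-2 convolution and a
residual stage; the `tiny` preset uses two stride-2 convolutions).
Three branches then compute features at 1/4, 1/8 and 1/16 scale. The
1/16 branch is flattened to tokens, augmented with learned 2-D
positional embeddings, and passed through a pre-norm multi-head
self-attention encoder — this is where long-range dependencies (e.g.
tail-tip-to-body relations) are modelled. All branches are brought to
1/8 scale (stride-2 convolution down, learned 2× deconvolution up),
concatenated, and fused by convolution; the four heads are 1×1
convolutions over the fused features. Two ablation switches
(`no_transformer`, `no_lrss`) remove a component without changing the
remaining head shapes.

Transformer defaults (4 layers, 8 heads, embedding 256 for the full
preset; 2/2/48 for `tiny`) are package choices at standard proportions;
so are the branch widths. The backbone is randomly initialised — no
pretrained weights are downloaded.

### Training

The loss is
$w_{\mathrm{hm}}\,\mathrm{RMSE}(\text{heatmaps}) +
 w_{\mathrm{lr}}\,\mathrm{RMSE}(\text{locref, masked}) +
 w_{\mathrm{seg}}\,\mathrm{CE}(\text{LRSS}) +
 w_{\mathrm{baf}}\,\mathrm{RMSE}(\text{BAF})$,
all weights defaulting to 1. RMSE is computed per head per sample and
averaged over the batch; cross-entropy is the per-pixel sparse
categorical form. Internally the network regresses stride-normalised
offsets (the interface stays in pixels) so that the locref and heatmap
losses live on comparable scales.

Optimisation is AdamW (decoupled weight decay $10^{-4}$) under a
warmup-cosine schedule: the learning rate ramps linearly from $10^{-5}$
to $10^{-3}$ over the first 10 epochs and cosine-decays back to
$10^{-5}$. The single-animal protocol runs 190 epochs at batch size 8
and stops early after a 30-epoch plateau of the validation loss
(5% split); the identity and social protocols run 300 epochs and
monitor the training loss instead. Augmentation is a similarity
transform applied jointly to image and keypoints; the identity protocol
samples rotation ±30°, translation x ∈ [−100, 100], y ∈ [−30, 15] px
and scale [0.9, 1.1]; the social protocol samples the translation only.
The default protocol's ranges (rotation ±25°, scale [0.75, 1.25]) are a
package choice in the style of standard keypoint-tool augmentation,
since only the protocol family is fixed.

### Decoding and identity

Single-animal decoding takes the global argmax per channel plus its
locref offset, rescaled by `1 / global_scale`. Social decoding extracts
up to `n_identities` local maxima per channel (greedy non-maximum
suppression, radius 5 cells), assigns each peak the majority identity
within a 3-cell window of the identity map, and keeps the
highest-confidence peak per (keypoint, identity). Peaks whose window is
all background are dropped and tallied. These radii are package
defaults, small enough to avoid cross-instance bleed at head
resolution.

Temporal identity correction is deliberately isolated behind one
function, since only its effect — not its algorithm — is fixed by the
method it implements. The package uses motion continuity: per frame,
instances are assigned to the previous frame's instances by minimising
summed center displacement (exact search over permutations up to 6
instances, greedy beyond); a relabel is accepted only when it beats
keeping the raw identity by more than a hysteresis margin (default
20 px), which prevents relabelling when animals are close and the
assignment is ambiguous. A sliding-window majority vote (15 frames)
then smooths each linked tracklet's label sequence. The operation never
touches coordinates or confidences and is idempotent.

### Mix-up social data

Multi-animal training frames are synthesised by hard compositing: with
background $B$ and single-animal frames $F_1, F_2$,
animal 1 keeps the pixels where $\max_{\text{ch}} |F_1 - B| \ge \delta$
(inclusive), animal 2 keeps the analogous pixels *not already claimed
by animal 1*, and $B$ fills the rest — every composite pixel comes from
exactly one source, no blending. $\delta$ defaults to 20 on 8-bit
intensities (a package choice; only the thresholding rule is fixed).
The merged annotation relabels the two instances as identities 1 and 2;
keypoints of animal 2 that land under animal 1's mask are marked
occluded, a package addition since the supervision of occluded merged
keypoints is otherwise unspecified. Hard compositing produces visible
seams — a realism limitation inherent to the approach, not an
implementation artefact.

## Evaluation metrics

For a track of $F$ frames, per keypoint:

* **drift fraction @ α** — $\tfrac1F \sum_{i=2}^{F}
  \delta(\lVert y_i - y_{i-1}\rVert > \alpha)$, default α = 50 px
  (mouse) / 30 px (monkey). The indicator counts *exceedances*; a
  `count_stable` flag flips it. The printed $1/F$ normalisation is kept
  even though only $F-1$ displacements exist.
* **miss fraction** — fraction of frames with confidence ≤ 0.2
  (inclusive).
* **identity change rate @ α** — the same exceedance count applied to
  each identity's center trajectory (default α = 75 px), averaged over
  identities. A single swapped frame between well-separated animals
  contributes two exceedances per identity.
* **PCK@0.15** — fraction of visible keypoints within $0.15\,L$ of
  ground truth; $L$ defaults to the square root of the visible
  bounding-box area (configurable per skeleton, e.g. a reference limb).
* **OKS** — $\mathrm{mean}_{v_i>0}\,
  \exp\!\big(-d_i^2 / (2\,\mathrm{area}\,(2s)^2)\big)$ with $s = 0.025$,
  implemented exactly in this printed form; a `mode = "coco"` flag
  provides the COCO-style per-keypoint-κ variant. Note the printed
  denominator makes OKS sharply scale-dependent: at desk-scale scenes
  (instance areas of a few hundred px²) even sub-pixel errors yield
  moderate OKS, so mAP values are not comparable across image scales.
* **AP@α / mAP** — AP is the fraction of instances with OKS *strictly*
  greater than α; mAP averages α = 0.50, 0.55, …, 0.95.
* **RMSE** — root mean squared Euclidean error, optionally restricted
  to predictions above a confidence cutoff (0.2 and 0.6 are the common
  reporting modes).

Every metric is mirrored by an independent brute-force oracle in the
test suite and checked on hundreds of random inputs, including the
boundary semantics (inclusive miss cutoff, strict AP threshold).

## The synthetic scene generator

Real labelled recordings are large and external; the generator renders
deterministic toy scenes instead: a 5-keypoint stick-figure animal
(nose, back = center, tail root, two paws) drawn as thick limb segments
plus an elliptical body, with a per-animal base colour, per-body noise
texture, and a small distinct-colour marker at each keypoint — the
desk-scale analogue of part-specific coat appearance. Backgrounds are
flat, gradient, or checkerboard, plus pixel noise. Scenes are pure
functions of (spec, seed).

Video mode moves each animal by a reflected random walk (step SD
1.5 px/frame) with slowly drifting heading; two-animal placement
enforces a configurable minimum center separation. Jump and
identity-swap events are injected *post hoc into the ground-truth
track only*, never rendered, so metric tests have exact expected
values.

What passing tests on this generator shows: the geometry of encoding
and decoding is exact; the network, loss and optimiser can fit a
learnable task end-to-end; the identity machinery resolves two
instances from its own targets. What it does not show: robustness to
fur, occlusion, lighting, motion blur, or appearance similarity of real
animals — the generator's textures are far more discriminable than real
coats, and its occlusions are absent by construction.

## Study conditions and problem sizes

The package's end-to-end checks run at a fixed desk scale, chosen once:
128 training frames of 64×64 px (plus 3 augmented copies each), 32
held-out frames, the `tiny` preset (~110k parameters), 150 epochs of
the warmup-cosine protocol at batch 8, and a 200-frame video for drift
measurement. At 64×64 the head map is 8×8; the heatmap σ is set to
1.2 cells there, because the default σ = 3 (appropriate when animals
span many map cells) would cover most of an 8×8 map. Two-animal
identity scenes use 128×128 px with a center separation of at least
2.8 body extents, so that same-keypoint peaks of different animals stay
outside each other's suppression radius; swap-injection videos use
192×192 px and 6 extents so that centers stay farther apart than the
75 px change-rate threshold throughout.

## Numerical choices and edge cases

* Coordinates are 0-based pixels, origin top-left, keypoint at pixel
  center; map cell $c$ corresponds to image position $c \cdot s$, so a
  keypoint exactly on that position peaks at 1 with zero offset and
  round trips bit-exactly.
* `NA` table cells mean "not annotated" (visibility 0), never (0, 0).
* LRSS/BAF overlap: instances are painted in listed order; earlier
  instances keep their cells.
* Identity ties in frame classification go to the lowest label; equal
  confidence peaks keep the first in scan order (both tallied).
* Inputs not divisible by 16 are zero-padded and the padding recorded.
* An all-zero heatmap channel decodes to confidence 0, not-detected,
  and an invalid-coordinate flag.
* RMSE losses guard the zero-loss point (gradient set to 0 instead of
  dividing by zero).
* The mean-squared-error toggle for the regression losses only rescales
  gradients; RMSE per head per batch is the default.

## Limitations

* The network is hand-written (conv/attention forward and backward in
  compiled code) and single-threaded CPU only; it is sized for method
  validation and small studies, not for GPU-scale throughput.
* Checkpoints store weights, not optimiser state; resuming continues
  with a fresh optimiser.
* Temporal identity correction assumes animals rarely teleport;
  prolonged total occlusion of one animal can defeat
  motion-continuity relabelling.
* The annotation readers support the native CSV layout and
  DeepLabCut-style CSV; HDF5 tables and video containers are not read —
  use image sequences.
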