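---
title: "Multimodal fusion for RGB-D fruit detection: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal fusion for RGB-D fruit detection: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Detecting fruit in orchards from a single RGB camera fails in exactly the
scenes where automation matters most: dense occlusion by leaves and
branches, night scenes under artificial light, and lens glare. A registered
depth channel is largely immune to lighting, but consumer depth sensors
produce *hollow noise* — rings of invalid (zero) pixels around object
boundaries — so naive summation or channel concatenation of the two
modalities injects as much noise as signal. `rgbdet` implements a
dual-stream detection scaffold built around two fusion blocks that address
both failure modes, together with everything needed to exercise them end to
end: a differentiable array engine, a synthetic aligned RGB-D scene
generator, YOLO-format dataset IO with joint mosaic augmentation, a full
mAP evaluation suite, and generate/train/evaluate/predict commands.

## The two fusion blocks

### Local-global enhancement (LGEM)

Feature grids are arrays indexed `(batch, channel, height, width)`. Given
per-stream features $RGB, Depth \in \mathbb{R}^{b,c,h,w}$, the block forms
the mixture $Local = \mathrm{concat}(RGB, Depth)$, compresses it to a
one-channel *local weight map* with a convolutional MLP,

$$E_{Local} = \mathrm{LN}\!\big(\mathrm{Conv}_{c/2\to1}(\mathrm{ReLU}(
  \mathrm{Conv}_{c/2\to c/2}(\mathrm{Conv}_{2c\to c/2}(x))))\big) \oplus
  \mathrm{Conv}_{2c\to1}(x),$$

(all convolutions 3x3, stride 1, padding 1, with bias; $\oplus$ is
elementwise addition), then globalises the map with single-head
self-attention over its spatial tokens,
$\mathrm{softmax}(qk^\top/\sqrt{d_k})\,v$ with $q = k = v$ the flattened
map, re-grids the result, applies a final 1-to-1 convolution, and
multiplies **both** streams elementwise by the resulting global map. The
multiplicative gate lets structure recovered from depth re-weight
light-polluted RGB regions, and vice versa.

Reading choices a user should know about:

* *Token convention.* A `(b, c, h, w)` grid flattens to `(b, h·w, c)`
  tokens: spatial positions are the token axis, channels the feature axis.
  This is the only reading under which $q k^\top$ is well formed for a
  one-channel map, and it makes `flatten_tokens()`/`upsample_tokens()`
  exact mutual inverses (a tested bit-exact round trip).
* *Bottleneck width.* The MLP bottleneck is half the per-stream channel
  count, so stream channels must be even; the constructor enforces this.
* *Layer norm.* Normalisation is over the channel-and-spatial extent of
  each sample, with a per-channel affine transform, which keeps the block
  independent of spatial size. It is applied to the main branch only,
  before the residual addition, exactly as the equation is written.
* *The final 1-to-1 convolution is bare* (no nonlinearity); nothing in the
  block's definition calls for one.
* *Single-head attention*; multi-head machinery is deliberately absent.

### Rough-fine attention fusion (RFAM)

Fusion proceeds coarse-to-fine. The coarse stage computes
cross-attention between the flattened streams — RGB queries attend over
depth keys/values and vice versa — and post-processes each attended stream
with its own bottleneck MLP

$$y = \mathrm{LN}\!\big(\mathrm{Conv}_{c/2\to c}(\mathrm{ReLU}(
  \mathrm{Conv}_{c/2\to c/2}(\mathrm{Conv}_{c\to c/2}(x))))\big) \oplus
  \mathrm{Conv}_{c\to c}(x),$$

applied along the token axis before re-gridding. Cross-attention lets each
modality fill its holes from the other at a semantic level: a depth void
ringed by valid structure can be reconstructed from RGB tokens that attend
to it.

The fine stage is coordinate attention: max pooling collapses each coarse
stream into a width profile `(b, c, w, 1)` and a height profile
`(b, c, 1, h)`; the four profiles are spliced (height profiles transposed)
into one mixed vector of length `2w + 2h`, transformed by a single shared
MLP of the same form, split back, and used to re-weight the streams:

$$Fused = RGB_R \circledast RGB_w \circledast RGB_h +
          Depth_R \circledast Depth_w \circledast Depth_h.$$

Choices a user should know about:

* *The $\circledast$ operator.* Read literally as matrix multiplication,
  $(h,w)\times(w,1)\times(1,h)$ products would change the spatial shape to
  $(h,h)$ and make the sum and every downstream consumer ill-formed. The
  default is therefore broadcast multiplication of each profile across its
  collapsed axis — standard coordinate-attention semantics, under which all
  printed shapes are consistent. `fine_fuse(..., method = "matmul")` keeps
  the literal reading available for experimentation.
* *No sigmoid on the profiles* by default, matching the written equations;
  `bounded = TRUE` applies one for users wanting classic bounded
  coordinate-attention weights.
* *Pooling subscripts name the retained axis*: the width profile pools out
  height, forced by the printed output shapes.
* *Parameter sharing.* The two coarse MLPs are independent; the
  mixed-vector MLP is a single shared instance — identical in structure to
  the coarse ones, not in weights.
* *Reversibility.* With the shared MLP set to the exact identity,
  `split_vectors()` inverts `mix_vectors()` bit-exactly; the test suite
  asserts this, and the identity MLP (zeroed main branch, dirac residual)
  is constructible via an internal helper.
* *Tri-modal extension.* Three streams fuse as
  $f = \mathrm{RFAM}(\mathrm{RFAM}(x,y), \mathrm{RFAM}(x,z))$ with an
  independently parameterised outer block; LGEM's tri-modal variant widens
  the mixture to $3c$ channels.

## The scaffold around the blocks

`build_model()` wires per-modality stage stacks (a stride-4 stem, then
three stages at strides 8/16/32), an LGEM at every stage, an RFAM fusing
every stage's outputs (channel concatenation + 1x1 projection when
disabled, the ablation baseline), an SPP-style pooled merge at the deepest
scale with a top-down neck, and per-scale heads emitting
`(4 box, 1 objectness, num_classes)` channels per cell. An optional
auxiliary stream re-consumes the RGB input through a pass-through
placeholder, splits the deepest fused feature with a 1x1 "CBLinear"
convolution, merges the upsampled parts into its own stages ("CBFuse"),
and contributes deep supervision during training only — it is skipped at
inference.

The stage blocks are deliberately plain residual-conv stacks, not replicas
of any published backbone's internals: the scaffold's contract is
topological (parallel streams, per-stage enhancement and fusion, auxiliary
flow), not weight-count-exact. Two stabilising choices are the package's
own: a sample-wise layer norm closes each stage and each neck merge, and
training clips the global gradient norm at 5. Both exist because the fine
fusion multiplies features by max-pooled feature profiles — a cubic
amplification per stage that otherwise compounds across the pyramid and
diverges within a few epochs.

Initialisation is also deliberate: the LGEM gate convolution starts at
weight 0, bias 1 (enhancement begins as the identity) and the RFAM MLPs
start as exact identities (zeroed main branch, dirac residual), so fusion
begins near pass-through and the blocks learn departures from it. Without
this, the multiplicative gate starts near zero and silences both streams.
The objectness head bias starts at -2, encoding the prior that most cells
contain nothing.

`count_params()` reports the closed form — $(K \cdot in + 1) \cdot out$
per convolution, $(in + 1) \cdot out$ per fully-connected layer,
normalisation affine terms enumerated — and always equals exhaustive
enumeration of the parameter arrays, a tested exact-integer invariant.

## Detection loss and assignment

The head decode is bounded: centre offsets are
$(2\sigma(t) - 0.5 + c)\,s$ and extents $(2\sigma(t))^2 \cdot 4s$ at
stride $s$, so a zero raw prediction emits the scale's base box and no
logit can produce an unbounded or degenerate box. Each ground truth is
positive at every pyramid scale, in the cells whose centres fall inside
the box within 1.5 strides of its centre (where the offset stays
decodable); this supervises the whole cluster of cells that will respond
to an object, which is what lets non-maximum suppression collapse them.
The loss is objectness binary cross-entropy with the positive and negative
cell populations balanced 1:1, class BCE on positive cells, and a box term
$1 - \mathrm{IoU}$ plus a small scaled centre-distance penalty (weight
0.2) so disjoint boxes still receive a gradient; the three terms combine
with weights 1 / 0.5 / 2. The box term's analytic gradient is verified
against finite differences in the test suite.

Training follows the reference recipe: Adam with first-moment coefficient
0.975, base learning rate 0.01 warmed up linearly from a 0.1x factor over
3 epochs then cosine-decayed, weight decay 5e-4, 640x640 inputs, batch 32,
200 epochs, and mosaic augmentation disabled for the final 30 epochs —
these are the `run_config()` defaults; desk-scale runs override the sizes.

## The synthetic generator, and what passing tests do not show

`generate_scene()` emulates the structure of orchard RGB-D imagery: a
textured foliage background; ellipse fruits biased toward the image
centre with small boxes; the four occlusion classes (unshaded, leaf,
branch, fruit) with a leaf-heavy default mix of 0.2/0.5/0.15/0.15; depth
encoding per-object distance via painter's order; dark-light and glare
corruptions of RGB only (depth is robust to lighting); and boundary
annulus voids at the depth sentinel 0 with configurable rate. Scenes are
bit-reproducible from config + seed, datasets are written 8:1:1 with a
manifest that regenerates them bit-exactly, and an optional near-constant
IR raster mimics the low information content of fruit infrared. A fruit
occluded by another fruit draws the occluder as unlabelled clutter so a
scene's label count stays exactly the configured fruit count.

The `"easy"` preset — 128x128 scenes, one or two large unoccluded fruits,
normal lighting, 10% void rate — is the benign end of the generator's
range and the condition for the end-to-end learning check: a tiny
dual-stream model (s-scaled 8/12/16 channels, ~68k parameters) trained for
20 epochs on 64 scenes, batch 4, must strictly decrease its smoothed
(5-epoch block) loss and reach validation mAP50 of at least 0.5. These
sizes keep the whole check inside a few minutes on one CPU and are stated
here as the package's chosen desk-scale protocol. The toy runs use Adam's
conventional first-moment coefficient 0.9 rather than the full recipe's
0.975: at a few hundred optimiser steps the high-momentum setting is
noticeably less stable, and 0.9 converges reliably across seeds.

What passing does **not** show: the generator has no photorealism, no real
sensor noise calibration, no motion blur, no correlated RGB-depth failure
modes, and its occluders are geometric primitives. Results on it say the
machinery learns and the contracts hold; they say nothing about accuracy
on real orchard data, and no accuracy figure from real-data experiments is
reproduced or claimed here.

## Evaluation conventions

Matching is greedy in descending confidence, one ground truth per
prediction, same class only, with a strict `>` IoU threshold. AP is the
area under the all-point-interpolated precision-recall curve — the
quantity mAP50 and mAP50:95 conventionally denote (mAP50:95 averages
exactly the ten thresholds 0.50-0.95). An accuracy-style alternative,
$(TP + TN)/(TP + TN + FP + FN)$ with $TN = 0$ (true negatives are
undefined for detection), is retained as
`average_precision(..., method = "accuracy")` for completeness, but plays
no role in the reported metrics. Precision and recall are defined as 0
when their denominators vanish. NMS defaults to IoU 0.5 and the prediction
confidence default is 0.25; both are conventions, configurable everywhere
they appear. Prediction confidence is the objectness alone, because class
logits are supervised only at positive cells and carry no ranking signal
elsewhere.

## Known limitations

* The compute engine is built for clarity and desk-scale problems;
  training beyond toy sizes is out of its intended envelope.
* `measure_speed()` is wall-clock and hardware-bound: a report-only
  convenience, never a comparison surface.
* Greedy matching can in principle differ from optimal assignment under
  adversarial overlap patterns; on well-separated detections (the regime
  the tests construct) the two coincide.
* Depth PNGs are written 8-bit, which quantises depth to 1/255 — ample for
  the generator's geometry but not a calibrated depth format.
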