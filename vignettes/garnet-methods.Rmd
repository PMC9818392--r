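---
title: "Guided attention residual networks for polyp segmentation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guided attention residual networks for polyp segmentation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
network and its loss, the parameters that matter, what the synthetic data
emulate (and do not), and the numerical and design choices made where the
architecture description left the design open.

## The segmentation problem

A colonoscopy frame is an RGB image; the task is a binary per-pixel
labelling (polyp vs. background). Clinically relevant failure modes drive
the design: small polyps vanish in deep, coarse feature maps; large ones
exceed any fixed receptive field; illumination gradients and specular
highlights produce false structure; and overlay text or color patches in
routine recordings are adversarial to texture cues. Encoder–decoder
networks with skip connections address resolution, but plain skips add
low-level noise back into the decoder, and a single broadcast attention map
(as in attention-gated U-Nets) modulates all channels identically, which is
both noisy early in training and wasteful of per-channel information.

## Architecture

`build_garnet(garnet_config(input_size, base_filters, depth, seed))`
assembles:

* **Stem** — one 3×3 convolution + batch norm + ReLU at full resolution,
  to `base_filters` channels.
* **Encoder** — `depth` *modified residual blocks*, each with two 3×3
  convolutions on the main path (conv→BN→ReLU→conv→BN), a single 1×1
  convolution on the skip path, stride 2 on both the last main convolution
  and the skip, sum, final ReLU. Stage widths are
  `base_filters * min(2^(i-1), 8)`; the 8× cap bounds the parameter count.
* **Bottleneck** — two plain residual blocks (identity skip, stride 1) at
  the coarsest resolution.
* **Decoder** — `depth − 1` stages. Each stage bilinearly upsamples the
  high-level maps ×2, projects them with a 3×3 convolution (+BN+ReLU) to
  the skip width, applies the guided attention module to (skip `L`,
  upsampled `H`), emits the consolidated attention map through the GAL
  head, concatenates the gated skip `O = A ⊙ L` with the upsampled maps,
  and fuses them with a stride-1 modified residual block.
* **Head** — a final ×2 upsampling stage *without* attention (there is no
  full-resolution encoder skip to gate), then a 1×1 convolution + BN +
  sigmoid producing the probability map.

With the reference 256-pixel input and depth 5 the attention maps land at
16, 32, 64 and 128 pixels — in general at `input_size / 2^(depth-i)` for
stage *i*. That ladder, with the stage-3 map at 64², is the anchor the
decoder reconstruction is built around; the alternative ladder one octave
finer would place stage 3 at 128² and is inconsistent with supervising the
stage-3 map against a 64² mask.

Where the published description is graphical rather than textual, this
package fixes the open choices as follows, once:

* main paths use exactly two 3×3 convolutions (the canonical residual
  design);
* the modified block's skip projection is 1×1 with the block's output
  width — the minimal learnable projection that matches shapes;
* upsampling is bilinear interpolation followed by a 3×3 convolution
  (transposed convolutions were rejected for their checkerboard artifacts);
* decoder fusion is channel concatenation, letting the fuse block learn the
  merge instead of hard-coding an addition;
* the bottleneck depth is two blocks;
* batch normalization precedes every nonlinearity, evaluation mode uses
  running statistics (biased variance, momentum 0.1, ε = 1e−5);
* weights are He-uniform, biases zero, all drawn from the config seed.

One genuine ambiguity deserves note: the module description says the
attention set is "multiplied elementwise with the up-sampled low-level
features", but elsewhere it is the *high-level* maps that are upsampled.
This package gates the skip (low-level) features, `O = A ⊙ L` — the
attention-gating reading, in which attention decides which spatially
precise detail survives into the reconstruction.

## The multi-task loss

`total_loss()` composes, and `train_garnet()` minimizes,

* soft dice on the main map, `1 − (2Σpg + ε)/(Σp + Σg + ε)` with
  ε = 1e−6 — the set-theoretic dice complement is undefined for
  probability-valued predictions, so the standard differentiable extension
  is used; ε makes the empty-vs-empty case equal 0 and nothing else
  measurably different;
* per-stage binary cross-entropy between each consolidated attention map
  and the ground-truth mask resized (nearest-neighbour, so it stays
  binary) to the map's resolution. The BCE is *averaged per pixel* rather
  than summed: the four maps differ 64-fold in pixel count, and an
  unnormalized sum would let the finest map dominate the objective. This
  is a deliberate normalization choice. Probabilities are clipped to
  `[1e−7, 1 − 1e−7]` inside the logarithms.

The total is exactly `main + sum(attention)` — the bundle's additivity is
bit-exact and tested.

A perfect attention map at a stage is the segmentation map at that stage's
resolution, which is why the resized mask is the supervision target: deep
supervision forces the attention maps to focus on the polyp region both in
early (fine) and late (coarse) decoder stages.

## Metrics

`evaluate_metrics()` binarizes predictions at a strict 0.5 threshold (the
binarization rule is a package convention; nothing in the method depends on
it) and reports per-image hard Dice `2TP/(2TP+FP+FN)`, mean IoU over the
foreground and background classes, and pixel accuracy, each averaged over
images. A class absent from both prediction and ground truth contributes
IoU 1 for that image. Whether published benchmark means are per-image or
pixel-pooled is generally unstated; per-image means are this package's
convention and are applied uniformly.

## Data pipeline

Training preprocessing resizes to `size + 14` (bicubic for the image,
nearest for the mask), augments, and takes a random crop at one of 15×15
offsets — at the reference size, 270→256. Evaluation uses a plain bicubic
resize to the input size, no augmentation. Masks are binarized at the 8-bit
pixel > 127 rule on read.

The augmentation stack applies, each with its own probability
(default 0.5): horizontal/vertical flips, scaling (factors 0.9–1.1),
rotation (0–90°), HSV saturation, brightness and contrast (factors
0.8–1.2), median/gaussian/motion blur (kernels 3 or 5) and gaussian noise
(σ ≤ 0.02). Magnitudes are conservative conventions, configurable in
`augmentation_config()`; none are prescribed by the method itself.
Geometric transforms use identical inverse-mapped coordinates for image and
mask; the mask is resampled with the same bilinear weights and re-binarized
at > 0.5, which keeps the pair *exactly* aligned (a nearest-neighbour mask
warp disagrees with a bilinear image warp on boundary pixels). Rotation
fills the image by reflection and the mask with zeros. Two alignment
caveats follow from these choices and are tested as such: intensity
transforms (brightness, contrast, blur) can move the soft edge a warp
creates across the 0.5 level set, and reflection can fold content back into
corner pixels, so exact image/mask threshold-alignment is guaranteed for
geometric transforms (with content away from borders), not for arbitrary
compositions with photometric ones.

Splits are seeded shuffles with `floor(0.1·n)` validation and test sizes
and the remainder in training: 800/100/100 at n = 1000, 490/61/61 at
n = 612.

## Training

Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e−8, no weight decay) with initial
learning rate 1e−4, batch size 4 and 120 epochs as reference defaults. The
validation loss is monitored after every epoch; after 10 epochs without
improvement the learning rate is multiplied by 0.1 (floor 1e−7) — the
plateau constants are package conventions, as only the technique itself is
prescribed. The same monitor selects the returned checkpoint: the epoch
with the lowest validation loss. There is no early stopping. Training
aborts on a non-finite loss, naming the offending batch.

## Synthetic data

`generate_dataset()` emulates the visual stressors discussed above rather
than photo-realism: a low-frequency textured reddish background, 1–3 bright
pink blobs whose elliptical boundaries are modulated by low-order angular
harmonics (radius 5–35 % of the image side), a linear illumination
gradient, small saturated highlight discs, an occasional white text-like
bar or green color patch in a corner, and gaussian pixel noise. The mask is
the exact union of the blob interiors. Generation is fully seeded and
byte-reproducible, and `allow_touching = FALSE` resamples blob placements
until supports are disjoint, making the component count exact for tests.

`generate_worked_pair()` is the parameter-free fixture: a centered circular
polyp of radius `size/4`. Its foreground count is known by exhaustive
lattice enumeration (12,892 pixels at size 256; 812 at size 64), which
anchors, e.g., the background accuracy 1 − 12892/65536 ≈ 0.8033 of an
untrained model whose output head is zeroed (every probability exactly
0.5, binarized to background under the strict threshold).

What passing tests on these images demonstrate: the architecture contracts,
the exactness of the loss/metric algebra, gradient correctness
(finite-difference-verified kernels), and that the full training loop —
multi-task loss, Adam, plateau scheduling, deep supervision — can drive a
reduced network (base width 8, depth 3) to memorize eight 64² pairs in 300
steps (train soft Dice ≥ 0.95) while the guided-attention loss falls by an
order of magnitude, i.e. the attention maps do converge toward the resized
masks. What they do not demonstrate: clinical performance. Real polyps
have texture continuity with surrounding mucosa, depth-of-field and motion
characteristics the generator does not model, and benchmark-level Dice/mIoU
requires the real datasets and full-length training.

The overfit demonstration deliberately uses a learning rate of 2e−2 —
memorizing eight images in 300 steps is an optimization stress test, not a
training recipe; the reference rate for real training remains 1e−4.

## Numerical choices and degenerate inputs

* Resampling (bicubic Keys a = −0.5, bilinear, nearest) is implemented as
  separable interpolation matrices with half-pixel centers and replicated
  edges; resizing to the same size is exactly the identity, and
  nearest-neighbour is the only mask-safe method.
* Strided convolutions use "same" zero padding of k⁄2, so output sides are
  `ceiling(h / stride)` for every input size, including odd ones.
* Sigmoid outputs are mathematically in (0,1); in double precision they
  saturate to exactly 0/1 for |x| ≳ 37, which the BCE clipping absorbs.
* Attention-map supervision requires the stage size to divide the mask
  size; violations, shape mismatches, channel mismatches, non-finite
  feature maps, unpaired dataset files and non-divisible configs all fail
  fast with messages naming the offender.
* Problem sizes in the shipped tests and the acceptance script (64–256 px
  inputs, widths 4–32, ≤ 300 optimization steps) were chosen so the whole
  verification suite runs on one CPU in minutes; they are reduced-scale
  instances of the same code paths the reference configuration uses.

## Known limitations

* Single foreground class; no multi-class head.
* No pretrained encoders; the package trains from scratch only.
* Training is single-device and full-precision; there is no gradient
  checkpointing, so the reference configuration at batch 4 is
  memory-hungry in R.
* The learning-rate plateau constants and the binarization threshold are
  conventions; results at benchmark scale could be sensitive to them.
* Depth-wise separable convolutions are intentionally not offered — they
  were reported detrimental to the attention mechanism in the source
  work's own ablation.
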