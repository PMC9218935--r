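---
title: "Half-UNet: models, accounting rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Half-UNet: models, accounting rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halfunet)
```

This vignette is the package's own account of what it implements: the
architecture family, the analytic complexity accounting, the training
protocol, the synthetic data, and every place where a design was genuinely
open and a choice had to be made.

## The segmentation problem and the architecture family

The package targets binary segmentation of square grayscale medical-style
images: one probability map per image, thresholded at 0.5 for evaluation.
All architectures are expressed as framework-independent `network_spec`
graphs of typed layer nodes (convolution, Ghost module, transposed
convolution, max pooling, bilinear upsampling, addition, concatenation),
so the same graph drives three consumers: shape validation, the analytic
complexity engine, and the CPU runtime.

**Half-UNet** rests on the observation that a U-shaped network's strength
comes mainly from its *divide-and-conquer* encoder — decomposing the input
into feature maps at downsample rates {1, 2, 4, 8, 16} — rather than from
the elaborate stage-by-stage feature fusion of its decoder. It therefore
keeps a five-stage encoder and replaces the whole decoder with one
*full-scale additive fusion*:

* channels are unified at 64 everywhere, so no channel-matching
  convolutions are ever needed;
* the five stage outputs are bilinearly upsampled to full resolution and
  summed — a fusion with no learnable parameters;
* two further blocks and a 1×1 sigmoid head produce the mask.

Every block is a **Ghost module**: a K×K convolution produces half of the
output channels (the intrinsic maps) and a cheap 3×3 depthwise convolution
of those maps produces the other half; the two halves are concatenated.
The comparison family consists of the canonical U-Net (channels doubling
64→1024, deconvolution + skip-concatenation decoder), a UNet3+-style
full-scale aggregation network, Half-UNet&dagger; (Ghost modules replaced
by plain 3×3 convolutions), the channel-doubling ablations
Half-UNet\*&dagger;~u~ / Half-UNet\*&dagger;~d~ (fusion channels unified by
upsample+conv or by deconvolution, respectively), and three ablation
encoders (A: contracting path only; C: the complete U-Net; B: a
best-effort mirror of the expanding path — see "Open reconstructions").

## Complexity accounting

The counting rules are deliberately minimal and are applied uniformly:

* conv: `(K²·Cin + 1)·Cout` parameters (drop the `+1` without bias),
  `2·K²·Cin·Cout·H·W` FLOPs on an H×W output (2 ops per
  multiply-accumulate);
* Ghost (s = 2, cheap kernel d = 3): primary conv at `Cout/2` plus
  `(d² + 1)·Cout/2` cheap parameters — equal to
  `[K²·(Cin+1) + 2]·Cout/2` when `d = K = 3`;
* transposed conv: parameters as a conv with its own K; FLOPs
  `2·K²·Cin·Cout·Hin·Win` with the *input* spatial size, which is why
  deconvolution-based fusion is FLOP-cheap but parameter-expensive;
* batchnorm: 2 learnable parameters per channel (scale, shift); running
  statistics are not learnable and are not counted;
* bias, batchnorm, activations, pooling, interpolation, addition and
  concatenation: zero FLOPs. This zero-costing is what makes Half-UNet's
  fusion stage literally free in the ledger.

Formatting uses K = 10³, M = 10⁶, G = 10⁹ with two decimals and
round-half-up; `round_half_up()` and `format_count()` are exported so
reported strings are reproducible. One known edge: a 3×3/64→64
convolution has exactly 36,928 parameters, which this rule prints as
"36.93 K"; the value is sometimes quoted truncated ("36.92 K").

Two calibration decisions were fixed by requiring the builders to
reproduce the published whole-network totals exactly:

* batchnorm + ReLU follow every 3×3 convolution and both Ghost stages.
  With it, U-Net totals 31,042,369 parameters ("31.04 M"); without it the
  total formats to 31.03 M. Half-UNet totals 207,329 + 1,536 batchnorm
  parameters = 208,865 ("0.21 M").
* the Ghost cheap operation is a biased 3×3 depthwise convolution — the
  `+2` in its parameter formula is precisely the two per-channel bias sets
  of the primary and cheap stages.

The Half-UNet decoder has exactly two 64-channel blocks after the fusion
plus the 1×1 head: this is the unique small topology that reproduces both
0.21 M (Ghost) and 0.41 M (plain conv) totals. In the channel-doubling
ablations the full-resolution tap is already at 64 channels, so it joins
the fusion without a unifying convolution, and the fusion deconvolutions
carry bias but no batchnorm; under those conventions the two variants
total 20,030,849 and 38,093,697 parameters ("20.03 M" / "38.09 M").

An independent oracle guards the whole engine: `verify_against_runtime()`
instantiates any network's weight containers and enumerates every
learnable scalar; the test suite asserts equality with the analytic totals
for all nine builders at several reduced configurations.

## Open reconstructions

Two structures are not fully pinned down by their published description
and are reconstructions:

* **UNet3+ decoder layers.** Each decoder layer here aggregates the five
  *encoder* taps (resample → 3×3 conv to 64 → concat to 320 → 3×3 conv
  320→320). This matches the channel arithmetic of the last fusion — the
  resampled inputs total 64+128+256+512+1024 = 1,984 channels — and the
  published sub-network ledger (aggregation conv 0.92 M / 30.20 G). The
  original UNet3+ chains decoder outputs into later layers instead; with
  deep supervision out of scope, the coarser aggregation layers here are
  side branches that count toward complexity but do not feed the single
  output. The five unifying convolutions give a fusion ("left") part of
  1.14 M / 37.45 G, slightly below the published 1.18 M / 38.66 G — the
  difference is exactly one 64→64 convolution at full resolution whose
  identity is unclear, so that cell is documented rather than asserted.
  The whole-network total of this reconstruction is 27.12 M vs the
  published 26.97 M.
* **Ablation encoder B** ("the expanding path used as an encoder") is
  implemented as: pool the input to the coarsest scale, map it to the
  widest channel count with a double convolution, then run
  deconvolution + double-convolution stages coarse-to-fine, tapping every
  scale for the shared aggregation head. It is flagged as a best-effort
  mirror, not a verified reconstruction.

## Runtime and training protocol

The runtime executes `network_spec` graphs directly: batched im2col + GEMM
convolutions (OpenBLAS), direct-loop depthwise convolutions, argmax-tracked
max pooling, half-pixel-centre bilinear interpolation, and a pure-GEMM
transposed convolution (stride = kernel, so output blocks do not overlap).
Backpropagation is hand-written per node and checked against central
finite differences in the test suite. Batchnorm uses batch statistics in
training (momentum 0.1, ε = 10⁻⁵) and running statistics at evaluation;
note that a bias feeding a batchnorm is absorbed by it and receives zero
gradient — such biases stay at their initial value and merely participate
in the parameter count.

`train_config()` encodes the reference protocol: Adam (β₁ = 0.9,
β₂ = 0.999), initial learning rate 0.001 for 60 epochs, Dice loss,
validation fraction 0.2, Kaiming initialization, and L2 regularization.
Choices the protocol leaves open, and what this package does:

* *"the rate is reduced by 2 and 10 at epochs 30 and 50"* is read as
  lr = initial/2 from epoch 30 and initial/10 from epoch 50
  (0.001 → 0.0005 → 0.0001). The compounding alternative (divide the
  current rate, ending at 0.00005) is available as
  `schedule_mode = "compound"`.
* the L2 strength is unstated; the default is 10⁻⁵ applied to convolution
  weights only (not biases or batchnorm), added to the Adam gradient.
* the validation split is a seeded random 0.2 fraction of the training
  set, drawn before shuffling; the six-repeat averaging convention is
  exposed as `repeats` but defaults to 1 at desk scale.
* the soft-Dice loss adds ε = 1 to numerator and denominator (per image,
  averaged over the batch), so empty masks are well-defined and a perfect
  prediction has exactly zero loss.

The best-validation-Dice epoch's weights are kept as the fit's
parameters; the final weights are also retained.

## Synthetic data

`generate_dataset()` emulates three regimes at their native sizes: a
single soft-edged, lightly textured bright ellipse at 128×128 (mass-like),
1–3 small bright discs at 64×64 (nodule-like), and a nested disc/annulus
at 256×256 producing two masks — inner disc (endocardium) and outer disc
(epicardium) — trained and evaluated independently. Masks are the *exact*
generating geometry: the soft intensity edge crosses its mid-threshold
precisely on the geometric boundary, so in the noiseless case a plain
threshold recovers the mask exactly (a test asserts this). Objects are
placed inside the inscribed circle with a 2-px margin so no rotation ever
clips foreground. Generation is a pure function of configuration + seed
and is byte-identical across runs.

What this does *not* emulate: real acquisition physics, anatomical shape
variability, annotation ambiguity (e.g. multi-reader agreement rules), or
class-imbalance structure of clinical datasets. Passing the training
acceptance on synthetic data demonstrates that the optimizer, gradients
and architecture wiring work — not clinical-grade segmentation ability.

Augmentation follows the tenfold scheme: per training image the original,
seven 45° clockwise rotations, one horizontal and one vertical flip.
Rotation keeps the canvas size with zero fill (multiples of 90° use exact
array permutations); images are interpolated bilinearly, masks by nearest
neighbour and re-binarized at 0.5. Under these conventions 90°-multiple
transforms preserve mask area exactly and 45°-multiples within a ≤5%
relative tolerance (asserted over generated masses). Splits follow the
7:3 train:test convention by a seeded permutation.

## Problem sizes used by the checks

The suite runs on one CPU. Oracle and property checks use reduced
configurations (depth 2–4, 4–8 base channels, 8–32 px) — parameter
identities are exact at any scale, and FLOP linearity is asserted across
two sizes. The six comparison architectures each complete a two-epoch
smoke train at 32×32 with 8 base channels. The training-quality check
trains canonical Half-UNet (full 64-channel width, depth 5) on the mass
regime at 64×64 — 150 images, 7:3 split, batch 14, 8 epochs, fixed seeds —
and requires held-out Dice ≥ 0.80; the complexity figures in the README
are computed at the full 1×128×128 configuration, where counts are exact
integers regardless of scale.

## Known limitations

* Only stride-1 "same" convolutions, 2ᵏ pooling/upsampling and
  stride = kernel deconvolutions are implemented — exactly what the family
  needs; dilated/strided convolutions, 3-D operators and other Ghost
  ratios (s ≠ 2) are rejected rather than guessed.
* The runtime is a correctness-first CPU engine (~0.1 s per 64×64 image
  forward+backward at full width); it is not meant for GPU-scale training
  or for reproducing accuracy tables on real clinical datasets.
* Dice aggregation is per-image averaging; dataset-pooled aggregation
  would weight large objects differently.
* FLOP accounting counts multiply-accumulates only; memory traffic,
  activation cost and wall-clock latency are out of scope.
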