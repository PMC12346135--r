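---
title: "Model, training objective and evaluation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, training objective and evaluation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The segmentation problem

B-mode ultrasound images of the kidney are grayscale, speckle-corrupted and
low-contrast, and the anatomical regions of interest are nested: the renal
capsule encloses the bright central echo complex (CEC), the dark medullary
pyramids and the intermediate-echogenicity cortex. The package addresses
two tasks over this anatomy: a 2-class task (background / capsule) and a
4-class task (background / CEC / medulla / cortex). Inputs are 2-D
grayscale images normalized to [0, 1]; outputs are per-pixel class
probability maps of the same spatial size.

## Network

The network is a U-shaped encoder–decoder with four skip connections.

**Encoder.** A stem of four (3×3 convolution → batch-norm → ReLU) units
lifts the 1-channel image to the base width (default 16). Four encoder
blocks follow; each applies a depth-wise 3×3 convolution (C→C), a group
3×3 convolution, and two plain 3×3 convolutions, every convolution followed
by batch-norm + ReLU. Depth-wise convolutions cannot change the channel
count, so the doubling that each encoder stage performs is assigned to the
group convolution (C→2C), leaving the two plain convolutions at full output
width. A 2×2 max pooling halves the spatial size after the stem and after
the first three encoder blocks — four poolings, matching the four skip
connections, with the bottleneck at 1/16 resolution.

**Pixel-wise attention gates.** At the end of every encoder stage, and of
every decoder stage, a gate module takes two streams: the primary features
*X* and a guidance stream *Y*. *Y* passes a 3×3 convolution (aligning its
channel count with *X*), then two 7×7 convolutions for a large receptive
field; batch-norm follows each convolution, ReLU the first two and a
sigmoid the last, producing a gate in (0,1) that multiplies *X*
elementwise. The wiring is a design decision the architecture description
leaves open: in the encoder, *Y* is the stage input (the pre-block
features) and *X* the block output — the gate is computed "from the input
features of the stage"; in the decoder, *Y* is the concatenated
(skip ⧺ upsampled) tensor and *X* the decoder-block output. This is the
only wiring in which the channel-aligning 3×3 convolution is doing real
work, since *Y* and *X* then always differ in width.

**Bottleneck self-attention.** Three parallel branches convolve the
bottleneck features (C = 16 × base width) with 3×3, 5×5 and 7×7 kernels,
each expanding C → 3C. Each 3C map splits channel-wise into equal Q, K and
V planes; spatial positions are flattened to tokens and multi-head
self-attention `softmax(QKᵀ/s) V` is applied per head (default 4 heads per
branch). The three C-channel outputs are concatenated and a 1×1 convolution
restores width C, so the bottleneck is width-neutral. The score normalizer
*s* is configurable: the default is `sqrt(d)` with *d* the per-head key
dimension (standard practice); `attention_scale = "d"` divides by the
per-head dimension itself and `"input_3c"` by three times the block's input
channels, honoring a published formulation whose normalizer is ambiguous
("three times the number of channels in the input image" — an image has one
channel, so the block's input feature width is the only meaningful
reading). For a 4-head, 256-channel bottleneck the three options give
s = 8, 64 and 768; smaller s sharpens the attention distribution.

**Decoder.** Each stage upsamples with a 2×2-kernel, stride-2 transposed
convolution (doubling H and W, halving C), concatenates the same-resolution
skip tensor, and applies a decoder block: depth-wise 3×3 (C→C), group 3×3
(C→C), point-wise 1×1 (C→C/2), each with batch-norm + ReLU. The channel
halving is assigned to the point-wise convolution, so the concatenated 2C′
features exit at the stage width C′. A 1×1 convolution + per-pixel softmax
head emits the class probabilities.

All convolutions use zero "same" padding (3×3→1, 5×5→2, 7×7→3), which is
required for the stated shape behavior and for skip concatenation. Inputs
must therefore have spatial sides divisible by 16 (2⁴ poolings).

**Parameters that matter.** `base_channels` (default 16) sets every stage
width by doubling; `groups = 4` for all group convolutions divides every
stage width from 16 to 256 (the architecture description never states a
group count); `heads = 4` per branch likewise. Kaiming fan-in
initialization with a caller-supplied seed makes builds reproducible.

## Objective and schedule

Training minimizes `L = λ·L_Dice + L_CE` with λ = 0.5. The Dice term is the
ε-smoothed soft Dice, `1 − mean_c (2Σp_c t_c + ε)/(Σp_c + Σt_c + ε)` with
ε = 1e-5, averaged over all classes including background (a flag excludes
it); batches are pooled into the per-class sums. The exact soft-Dice form
is a design decision — the source protocol names Dice loss without defining
it — and ε prevents 0/0 for classes absent from both prediction mass and
target. Cross-entropy is the mean per-pixel negative log-likelihood,
computed from pre-softmax scores via a stable log-sum-exp; optional class
weights are exposed for class imbalance but default to none. The
learning rate follows `lr = lr₀(1 − t/T)^0.9` per iteration (lr₀ = 0.01,
T = 30000 at reference scale), stepped every iteration because the protocol
counts iterations, not epochs. The optimizer is SGD with momentum 0.9 and
weight decay 1e-4.

The gradient engine is a small reverse-mode tape over (H, W, C, N) arrays;
convolution forward/backward run through im2col and BLAS matrix products in
compiled code. Correctness is established by finite-difference tests at the
loss level and end-to-end through every layer type.

## Metrics

DSC = 2|A∩B|/(|A|+|B|) and IOU = |A∩B|/|A∪B| (reported ×100) satisfy
IOU = DSC/(2−DSC) identically. Surface distances use the 4-connectivity
boundary (a mask pixel with any 4-neighbor outside the mask, or on the
array border); distances are Euclidean, in pixels unless a physical pixel
spacing is supplied — published tables in this area report millimetres
without stating the pixel-to-mm mapping, which cannot be recovered from the
images, so pixel units are the honest default. HD95 has two modes: the
default percentile mode takes the 95th percentile (linear interpolation
between order statistics) of the pooled directed surface distances in both
directions — the standard definition, matching the textual description
"95th percentile instead of the maximum" — while the literal mode computes
0.95 × the exact bidirectional Hausdorff maximum, exactly as one published
formula prints it; the two disagree whenever the distance distribution is
not degenerate at its maximum. ASD divides the summed directed distances by
|S(A)|+|S(B)|. Empty masks make distance metrics undefined: such cases are
flagged and excluded from means with an exclusion count, while DSC/IOU use
the 1-if-both-empty, 0-if-one-empty convention. Method comparison uses the
two-sided paired t-test per case; all-zero differences give p = 1 by
convention and a nonzero constant difference is an error (undefined
statistic).

## Synthetic phantoms

The generator emulates the structure of kidney B-mode images: a rotated
outer ellipse (capsule) with jittered center, axes and rotation; a
concentric inner ellipse (CEC) at 0.35–0.45 of the outer axes; 4–8 dark
lobes placed in the annulus between CEC and rim (medulla); the remaining
interior as cortex. Echogenicities are ordered as in renal sonography —
CEC 0.75 (brightest), cortex 0.45, medulla 0.25, background 0.15 — so class
appearance, not just geometry, carries label information. The map is
Gaussian-blurred (σ = 1.5 px) and multiplied by unit-mean gamma speckle
with standard deviation 0.4, a standard first-order model of B-mode
speckle, then clipped to [0, 1]. Default size is 256 (any multiple of 16
works; tests use 48–64 to stay CPU-friendly). Phantoms are a pure function
of (spec, seed).

What the phantom does **not** model: point-spread-function convolution
physics, depth-dependent attenuation and shadowing, operator variability,
and the irregular, low-contrast boundaries of real kidneys. Passing tests
on phantoms therefore demonstrate that the implementation is correct and
that the architecture can learn nested anatomies under multiplicative
noise — not that the published clinical accuracy transfers.

## Pipeline

Preprocessing center-crops or zero-pads to a square (default 512, the
reference crop; zero-padding preserves all content of smaller images, a
choice the protocol leaves open) and min-max normalizes to [0, 1], mapping
constant images to zero. Augmentation — rotation within ±25°, horizontal
and vertical flips at probability 0.5, additive Gaussian noise with σ up to
0.05, brightness/contrast jitter ±0.2 — applies the geometric part
identically to image (bilinear) and mask (nearest-neighbor) and the
photometric part to the image only; the magnitudes are unstated in the
reference protocol and are configurable. Dataset splitting excludes
subjects missing a required class, then shuffles under a required, logged
seed ("random split" with no stated seed otherwise being unreproducible).
Training cycles the samples in seeded shuffled order indefinitely
(iteration-counted training with no epoch notion), evaluates mean
foreground DSC on the validation set every 250 iterations by default, and
retains the state with the highest validation DSC.

## Scaled-down experiments

The reference protocol (512×512 crops, batch 4, 30000 iterations) is a
multi-day CPU computation, so the package's standard capacity experiment
runs the full architecture at width 8 on eight 64×64 capsule phantoms for
300 iterations with batch size 2 — small enough for minutes on one core,
large enough that the network must actually fit the geometry. The batch
size of 2 is the package's small-experiment default. Under these
conditions the trained network reproduces the training masks at mean
foreground DSC ≈ 0.98 (the acceptance script recomputes this from scratch),
comfortably above the 0.90 capacity threshold the tests assert.

## Numerical choices and degenerate cases

- Batch-norm follows each convolution before its activation, uses biased
  batch variance for normalization, unbiased updates of running statistics
  (momentum 0.1), and running statistics at inference.
- Attention softmax subtracts the row maximum before exponentiation; a
  single-token bottleneck reduces attention exactly to its V pass-through,
  and the implementation is tested against that closed form.
- Very small inputs can make a bottleneck batch-norm reduce over one
  element, collapsing its activation onto the (zero-initialized) shift
  parameter — exactly on the ReLU kink. Gradient tests therefore use
  inputs whose bottleneck retains at least 2×2 tokens; practical inputs
  (≥64 px) are unaffected.
- Flip equivariance: a convolution satisfies
  `conv(flip x, w) = flip(conv(x, flip w))`, so a network with generic
  kernels is *not* equivariant to mirroring. What is true — and what the
  test suite asserts on ten random builds — is that the network becomes
  exactly flip-equivariant once every kernel is left-right symmetrized.
  This is the sharpest form of the property the architecture supports, and
  it pins down the absence of spatial off-by-one asymmetries in padding,
  pooling tiles, the transposed convolution and token attention.
- The reference subject counts for the capsule task (341/49/97 of 481) do
  not sum to their stated total (487 ≠ 481); `split_dataset()` enforces
  that counts sum to the post-exclusion subject count rather than
  reproducing the inconsistency.

## Known limitations

Pure-R-plus-BLAS training is orders of magnitude slower than a GPU
framework; the package targets correctness, inspectability and small
controlled experiments, not full-scale benchmark training. No 3-D variant,
no pretrained weights, no mixed precision, and metrics are 2-D only.
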