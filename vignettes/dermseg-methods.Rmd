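---
title: "Hybrid CNN-transformer lesion segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid CNN-transformer lesion segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermseg)
```

## The problem

Dermoscopic lesion segmentation assigns every pixel of a magnified skin image
to lesion or background. Two properties of this task shape the architecture
implemented here. First, lesions vary enormously in scale — from a few dozen
pixels to most of the frame — so purely local (convolutional) features miss
the global shape of large lesions, while global attention at full resolution
is quadratically expensive in the number of pixels. Second, the boundary is
the clinically relevant structure, and it competes with high-frequency
nuisance signal: hair, skin texture, illumination seams.

`dermseg` implements a lightweight U-shaped encoder-decoder addressing both:
multi-scale query attention in every stage for global context at
sub-quadratic cost, and a wavelet-domain attention gate on the
highest-resolution skip connection for boundary refinement. All layers,
including the backward passes, are implemented natively in R on top of BLAS
matrix products; gradient correctness is established by finite-difference
tests for every layer and for the assembled network.

## Building blocks

**Residual depthwise-separable CNN block.** For input $X \in
\mathbb{R}^{B\times C\times H\times W}$:

$$Z = X + \mathrm{ReLU}(\mathrm{BN}(\mathrm{Conv}_{1\times1}(
      \mathrm{ReLU}(\mathrm{BN}(\mathrm{DWConv}_{7\times7}(X))))))$$

The $7\times7$ depthwise convolution (one filter per channel, zero padding 3,
stride 1) gathers spatial context cheaply; the $1\times1$ convolution mixes
channels. The block is shape preserving, which the residual requires; channel
changes happen only in the stage-transition samplers. The residual addition
carries no activation. In evaluation mode batch normalisation uses stored
running statistics (momentum 0.1 during training), so inference is
deterministic.

**Multi-scale query attention (MSQFormer).** The input map is flattened to
$N = HW$ tokens. Queries keep full resolution; keys and values are computed
from spatially compressed copies at strides $s_i \in \{2, 4, 8\}$, produced
by convolutions with kernel = stride (no padding), giving $M_i = HW/s_i^2$
tokens per path. Each path receives $h/2$ heads of dimension $d = C/h$, so
the query projection emits $3C/2$ features — the only reading under which the
concatenated path outputs (width $3C/2$) project back to $C$. Per path:

$$K_i, V_i = \mathrm{Split}(\mathrm{Linear}(\mathrm{GELU}(\mathrm{LN}(F_i)))),
\qquad
\tilde V_i = V_i + \mathrm{DWConv}_{3\times3}(V_i)$$

$$\mathrm{SA}_i = \mathrm{softmax}\!\left(\frac{Q_i K_i^\top}{\sqrt d}\right),
\qquad Z_i = \mathrm{SA}_i \tilde V_i$$

and the three $Z_i$ are concatenated and linearly projected back to $C$
channels with (configurable, default 0) dropout, wrapped in a residual
connection. Attention score memory per path is $N \times M_i$, strictly below
the $N^2$ of plain self-attention for every $s_i \ge 2$; a test asserts the
allocated score sizes equal $N(M_1 + M_2 + M_3)$. The block has no
feed-forward sub-layer and no positional encoding — it is residual attention
only — and the queries get a LayerNorm mirroring the key/value path, which
stabilises training. A single-scale ablation keeps only the stride-2 path.

**Wavelet-attention refinement (WARM).** The highest-resolution encoder skip
$X_{enc}$ is decomposed by a single-level orthonormal Haar DWT into four
half-resolution sub-bands $(ll, lh, hl, hh)$; the upsampled decoder feature
is average-pooled to the same size as a guidance signal $g$; each sub-band is
gated by its own attention gate

$$A(x_{sub}, g) = x_{sub} \odot
  \sigma(W_\psi\,\mathrm{ReLU}(W_x x_{sub} + W_g g))$$

with a single-channel attention map broadcast over channels, and the gated
sub-bands are recombined by the inverse transform. The Haar basis is chosen
because it gives exact reconstruction with two-tap kernels and matches the
half-resolution sub-band layout; orthonormality means the gates can only
attenuate sub-band energy, never amplify it. The gate embedding width is a
calibrated configuration parameter (default 152; `max(C/2, 1)` is the
sensible stand-alone choice). Because gating is sigmoid-bounded in $(0,1)$,
saturating the $\psi$ bias recovers an identity (or annihilating) skip,
which the tests exploit.

## Network assembly

A $3\times3$ stride-2 stem lifts RGB to the first stage width at half
resolution; four encoder stages of [CNN block → attention block] pairs are
connected by $2\times2$ stride-2 convolutions (channel expansion), mirrored
by a decoder using $2\times2$ transposed convolutions (channel reduction).
Skips from encoder stages 1–3 fuse into the decoder by element-wise addition;
the stage-1 skip passes through WARM first, guided by the upsampled decoder
feature. The bottleneck has no skip. A $2\times$ transposed convolution and a
$1\times1$ head restore input resolution with one logit channel.

The stem stride deserves a note: with attention in *every* stage, running
stage 1 at the full 256×256 grid would put $N = 65536$ tokens into the
attention paths and push the model far beyond its complexity budget; halving
first keeps stage-1 attention at $N = 16384$ and is what makes all-stage
attention affordable. The required input divisibility is
`stem_stride * 2^(stages-1) * 8` (the stride-8 path needs the deepest grid
divisible by 8) — 64 for the default.

### Calibration of the default configuration

The reference complexity budget for this architecture at 256×256 input is
5.76 M parameters / 7.51 G MACs in total, 4.63 M in the encoder and 0.04 M in
WARM. Only the deepest width (128) and these totals are fixed; per-stage
widths and depths are free. They were calibrated once against the budget by a
grid search over widths and depths (`profile_network()` is analytic, so the
search is seconds): the shipped default is widths `c(32, 56, 80, 128)`,
encoder depths `c(1, 1, 2, 2)`, decoder depths `c(1, 1, 1)`, heads
`c(2, 4, 8, 8)`, gate width 152, which lands at 5.722 M total, 4.636 M
encoder, 0.0401 M WARM and 7.435 G MACs — all within 1.3% of the budget. The
decoder share (1.046 M vs 1.12 M, −6.6%) is the one number that cannot be hit
simultaneously: additive skip fusion forces decoder stage widths to mirror
encoder widths, which couples the two budgets. Decoder depth 1 per stage is
the calibration's resolution of the open question whether the decoder mirrors
the encoder's depth. MAC accounting counts one multiply-accumulate as one
FLOP (the convention of lightweight-model reporting) and assigns zero cost to
normalisation, activations, pooling and the wavelet transforms.

## Loss and metrics

Training minimises $w_{ce}\,\mathrm{BCE}(\sigma(z), g) + w_{dice}(1 -
\frac{2\sum pg + \epsilon}{\sum p + \sum g + \epsilon})$ with $p =
\sigma(z)$, $\epsilon = 1$ and default weights $1:1$ (the smoothing constant
and weighting are conventional choices; the combination of cross-entropy and
Dice is the protocol's). BCE uses the numerically stable logits form; the
Dice term is computed over the whole batch.

Evaluation reports mIoU (mean of background and lesion IoU, $k = 1$
foreground class), DSC, accuracy, sensitivity and specificity from confusion
counts pooled over the evaluation set, plus per-image HD95 summarised as mean
± sd. Conventions, all exercised by tests: probability threshold 0.5; a class
absent from both masks contributes the defined value 1 (else 0) wherever its
denominator vanishes; HD95 pools the directed boundary distances in both
directions and takes the 95th percentile with R's default (type 7)
interpolation; boundary pixels are mask pixels with a background 4-neighbour,
with outside-image treated as background; if exactly one mask is empty the
image diagonal is returned as a sentinel and counted separately; if both are
empty, 0.

## Training protocol

AdamW (betas 0.9/0.999, decoupled weight decay $10^{-2}$) with cosine
annealing $lr(t) = lr_{min} + \frac{1}{2}(lr_0 - lr_{min})(1 + \cos(\pi
t/T))$, $lr_0 = 10^{-3}$, $lr_{min} = 10^{-5}$, $T = 300$ epochs, batch
size 2. Augmentation applies the same transform to image and mask:
horizontal/vertical flips with probability 0.5 each and rotation uniform in
±30° (bilinear with reflection padding for the image, nearest-neighbour for
the mask so it stays binary); the flip probabilities and angle range are this
package's choices where the protocol names only the transform families. A
global gradient-norm clip (default 5) guards the hand-rolled optimisation
against rare spikes; directory datasets are split 70/30 with a seeded
shuffle; the retained checkpoint maximises validation (else training) DSC.
All randomness derives from the configured seed.

## Synthetic data

The generator emulates the *structure* of dermoscopy data so the pipeline is
testable without downloads: one lesion per image, binary mask, skin-tone
background. Lesion boundaries are radial Fourier curves $r(\theta) = r_0(1 +
\sum_k a_k \cos(k\theta + \phi_k))$ with $\sum a_k$ capped below 1 — smooth,
star-convex, hence guaranteed single-component masks with controllable
irregularity. Images add Gaussian skin texture, a mean lesion/skin intensity
gap equal to the configured contrast, dark anti-aliased cubic-Bézier hair
strokes, and a multiplicative linear illumination gradient. Defaults (radius
15–40% of the frame, contrast 0.35, texture sd 0.03, 0–8 hairs, ±10%
illumination) are fixed once as plausible dermoscopy-like values. What it
does **not** emulate: real chromophore color distributions, multi-lesion
scenes, ruler/gel artifacts, camera noise. Passing the overfit test therefore
demonstrates that the architecture, gradients and optimiser work — not
clinical-grade performance on real dermoscopy.

## Desk-scale problem sizes

The test suite and the worked examples run entirely on CPU, so they use
deliberately small instances: oracle comparisons on $8\times8$ grids
($N \le 64$ tokens), metric oracles on $20\times20$ masks, and a learning
smoke test that overfits 8 synthetic 64×64 images with a 3-stage model
(widths 8/16/32, ~164 k parameters) for at most 200 epochs — it reaches
training DSC ≥ 0.95 with a ≥10× loss reduction in a few minutes. The full
256×256 default model runs forward inference in seconds and its profile is
analytic; nothing in the package requires a GPU.

## Known limitations

- Pure-R training is orders of magnitude slower than a compiled framework;
  the package is built for correctness, desk-scale experiments and
  architecture analysis, not for 300-epoch benchmark training.
- Deterministic reproducibility holds for a fixed R/BLAS build; different
  BLAS implementations may differ in the last bits.
- JPEG input requires the optional EBImage package; PNG is native.
- The mIoU aggregation pools confusion counts over the evaluation set;
  per-image averaging would differ on heterogeneous sets.
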