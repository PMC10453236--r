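---
title: "GC-TransUnet: model, design choices, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GC-TransUnet: model, design choices, and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gctransunet)
```

## The model

GC-TransUnet is an encoder--decoder network for binary medical image
segmentation (skin lesions, colon polyps) whose encoder treats patch
relationships *distance-aware*: nearby patches interact through local
windowed self-attention, while distant content reaches each window through
a small set of distilled global tokens, instead of uniform all-pairs
attention or shifted-window schemes.

**Encoder.** A stride-4 convolutional stem (kernel 4, non-overlapping
patches) embeds the RGB image into `base_dim` channels and refines it with
one Fused-MBConv block. Four hierarchical stages follow. Stage $i$ works
at side $S_i = \mathrm{input}/4/2^{i-1}$ and width $C_i = 2^{i-1}
\cdot \mathrm{base\_dim}$, and runs `stage_depths[i]` pre-norm transformer
blocks

$$x \leftarrow x + \mathrm{MSA}(\mathrm{LN}(x)), \qquad
  x \leftarrow x + \mathrm{MLP}(\mathrm{LN}(x)),$$

alternating **local** blocks (queries, keys and values all from the same
$w \times w$ window) with **global** blocks, whose queries come from the
stage's *Global Token Generator* (GTG). Attention is the scaled dot
product with a learned relative position bias,

$$\mathrm{Attention}(Q, K, V) =
  \mathrm{softmax}\!\left(\frac{QK^\top}{\sqrt{d}} + b\right) V,$$

with $d$ the per-head dimension and $b$ indexed by the in-window
displacement between query and key positions (a $(2w-1)^2 \times
\mathrm{heads}$ table). The GTG reduces the stage map to exactly $w^2$
tokens by $\log_2(S_i / w)$ repetitions of Fused-MBConv + $2\times 2$
max-pooling, and is evaluated **once per stage**, its tokens shared by all
of that stage's global blocks. Between stages, a downsampler
(Fused-MBConv, layer norm, then a $3 \times 3$ stride-2 convolution)
halves the side and doubles the width. The Fused-MBConv block itself is

$$\bar{x} = \mathrm{Conv}_{1\times 1}(\mathrm{SE}(\mathrm{GELU}(
  \mathrm{DWConv}_{3\times 3}(x)))) + x,$$

so it degenerates to the identity when its final projection is zero -- a
property the tests assert exactly.

**Bridge and decoder.** After stage 4 (side input/32, width
$8\,\mathrm{base\_dim}$) a *patch expand* step widens channels linearly
($C \to 2C$) and redistributes them into $2 \times 2$ spatial blocks --
net side $\times 2$, channels $\div 2$ -- and *ConvMore* ($3\times3$ conv
+ batch norm + ReLU) maps the result to the decoder width (512 by
default). The decoder performs four steps of bilinear $2\times$
upsampling, concatenation of a CNN skip feature (first three steps only),
and a $3\times3$ conv + batch norm + ReLU halving the working width
($512 \to 256 \to 128 \to 64 \to 64$), then a $1\times1$ projection to the
class logits. The skip features come from a separate convolutional branch
-- a $7\times7$ stride-2 stem plus three residual bottleneck blocks --
producing maps at sides $H/2, H/4, H/8$ with widths 64/128/256. With one
output channel the network trains with a sigmoid and soft dice loss.

## Configurations and tunable parameters

`get_config("gcvit-t")` is the tiny variant: width 64, depths
[3, 4, 19, 5], heads [2, 4, 8, 16], windows [7, 7, 14, 7], MLP ratio 3,
patch size 4, native input 224. `"gcvit-b"` doubles widths and windows
([12, 12, 24, 12]) at MLP ratio 2 and is native to 384-pixel inputs; the
validator enforces this geometry rather than silently resizing, since the
window sides must divide the stage sides and their ratio must be a power
of two (the GTG pooling constraint). A desk-scale `"toy"` variant (width
8, depths [2, 2, 2, 2], windows [4, 4, 2, 2], 64-pixel inputs) exists so
that the full pipeline -- including training -- runs in seconds to
minutes on one CPU core; tests use it throughout.

Parameters a user may care to change, with defaults and units:

* `learning_rate = 0.001`, `batch_size = 6`, RMSprop with `alpha = 0.99`,
  `eps = 1e-8`, no momentum or weight decay: the training recipe. Only the
  rate and batch size are prescribed by the method; the remaining RMSprop
  constants are the standard defaults and are exposed in
  `train_settings()`.
* `se_reduction = 4` (dimensionless): the squeeze-excitation bottleneck
  ratio. The method description leaves it open; 4 is the standard choice
  at these widths.
* `gn_groups = 1`: group-norm group count in the CNN branch (eps 1e-6).
  One group normalises over all channels jointly and stays valid for
  every toy width; the count is configurable.
* `smooth = 1e-6`: dice-loss smoothing, which bounds the loss at perfect
  overlap by `smooth / (2|t| + smooth)`.
* Ablation toggles (`use_local_attention`, `use_global_attention`,
  `use_gtg_feature_extraction`, `use_fused_mbconv_downsample`,
  `use_patch_expand`): each reproduces one published ablation variant with
  a single flag. The attention toggles substitute the other block kind
  (identical projection shapes, so the parameter count is unchanged); the
  other three strictly remove parameters.

## Design choices where the description was open

These are this package's own resolutions of genuinely underdetermined
points, chosen once and fixed:

* **Attention scaling.** The attention formula is implemented as
  $QK^\top/\sqrt{d}$ with $d$ the per-head width -- the standard scaled
  dot product of the vision-transformer lineage this architecture extends.
* **Relative position bias everywhere.** The bias term appears in both
  local and global attention; for global attention the token distilled
  from grid position $(i, j)$ is assigned the displacement it would have
  at window position $(i, j)$, which keeps one index map for both kinds.
* **Block order.** Pre-norm residual blocks, alternation starting with a
  local block (so odd depths end local); global attention output re-enters
  the residual stream before the MLP, the standard block order.
* **Stem depth.** One Fused-MBConv refinement after the patch embedding.
* **Downsampler norm placement.** Layer norm sits after the Fused-MBConv
  and before the strided convolution, normalising over channels.
* **CNN branch strides.** The three residual blocks are described with
  stride-1 convolutions, which cannot produce the three-scale skip
  pyramid the decoder consumes; stride 2 is placed on the 3x3 convolution
  of blocks 2 and 3 (the hybrid-encoder convention), which the decoder's
  H/16 -> H arithmetic requires. Bottleneck inner width is half the block
  output width; with ResNet's classical quarter-width bottleneck the
  branch would undershoot the published compute budget (see below).
* **Decoder.** One 3x3 convolution per upsampling step, skip fusion by
  channel concatenation, no skip on the fourth step (three skip
  connections total), batch norm in the decoder and ConvMore, group norm
  in the CNN branch.
* **GTG details.** 2x2 stride-2 max pooling (the power-of-two geometry
  forces 2x reduction per step), one Fused-MBConv per pooling step, and a
  row-major reshape to sequences that matches the window-partition token
  order so bias indexing aligns.
* **A 1x1 convolution listed with padding 1** in the published GTG layer
  table would grow the spatial size; it is read as padding 0.
* **Metric definitions.** The six reported statistics are not given
  formulas; the standard semantic-segmentation definitions are used, with
  "midce" read as mean dice over the evaluation set (it equals F1 for
  binary masks, which the tests cross-check). Metrics are computed
  per image then averaged; a class absent from both prediction and truth
  contributes 1 to its ratio (configurable). Whether to pool pixels
  instead is exposed through `compute_metrics` on concatenated masks.

The architecture reconstruction was calibrated against the published cost
figures (33.13 M parameters, 11.72 GFLOPs at 224 px): parameter-free
choices above were fixed first, and the two remaining free widths (the
bottleneck inner width and the decoder schedule) were chosen so the
assembled network lands within about 1.5% of both numbers
(`count_complexity(gc_transunet("gcvit-t"))`). FLOPs use the
multiply-accumulate convention (convolution $k^2 C_{in} C_{out} H_o W_o$;
linear $C_{in} C_{out}$ per token; attention counts its two matrix
products; normalisations, activations, pooling and interpolation are not
counted), the convention under which the published magnitudes are
consistent with peer tools. Note the doubled convention (2 FLOPs per MAC)
also exists.

## Numerical choices

* All tensors are dense base-R arrays, channel-last `(B, H, W, C)`;
  convolutions run as im2col + BLAS GEMM; every backward pass is an
  analytic reverse-mode derivative, verified against central finite
  differences in the test suite (discrepancies at large step sizes are
  ReLU/max-pool kink crossings, not gradient errors).
* GELU is exact ($x\Phi(x)$), not the tanh approximation.
* Softmax subtracts the row maximum before exponentiation.
* Max-pool ties route the gradient to the first slice in scan order.
* Bilinear resampling uses half-pixel centres with clamped edges and is
  exact on constants; masks are resized nearest-neighbour and
  re-binarised at 0.5 so labels never bleed.
* Batch norm keeps running statistics (momentum 0.1) for evaluation mode;
  training mode uses batch statistics.
* Weights initialise from a truncated normal (sd 0.02); the RNG stream is
  fully determined by the seed, and training shuffling derives from
  `train_settings()$seed`, so runs are bitwise reproducible.

## What the synthetic fixtures emulate -- and what they do not

`generate_dataset()` produces one smooth bright-or-dark blob per image: an
ellipse whose radius is modulated by a truncated low-order Fourier series
in angle, coloured away from a textured background by a configurable
mean-intensity margin (default 0.25), over low-frequency texture plus
pixel noise, with the exact binary mask. This mimics the single-lesion /
single-polyp structure of dermoscopy and colonoscopy benchmarks --
irregular contours, varying scale (area fraction 5--20% by default),
varying contrast -- while remaining seeded and generable in milliseconds.

It deliberately does **not** reproduce specular highlights, hair and
instrument artefacts, multi-instance or rim-like lesions, or
class-imbalanced edge cases of real data. Passing the learning smoke test
(a toy model overfitting four 64-pixel samples to dice at least 0.95
within 200 RMSprop epochs at rate 0.001) therefore shows that the
architecture, gradients and optimiser are wired correctly -- not that the
network reaches any particular accuracy on real dermoscopy or endoscopy
images, which requires the original datasets and GPU-scale training.

## Problem sizes used by the tests

The suite exercises the full 224-pixel tiny configuration only where the
contract is about that geometry (architecture cost; one forward pass for
the /32, /16, /1 shape law). Everything else -- oracle equivalences,
structural identities, training -- runs on toy geometries (windows of
side 2--4, at most 4 windows, 2 heads, 64-pixel images), where
brute-force oracles are exact and fast. The 200-epoch smoke training run
takes about two minutes on one CPU core.

## Known limitations

* CPU-only and single-threaded apart from BLAS; full-resolution training
  is out of reach (by design -- the package's purpose is a correct,
  testable reference implementation, not a training harness for GPUs).
* Binary segmentation is the first-class path (`num_classes = 1`,
  sigmoid + dice); multi-channel logits are produced but multi-class
  training utilities are not provided.
* JPEG decoding is not available in this environment's image stack;
  dataset I/O is PNG (the fixture writer emits PNG, and the loaders
  accept exactly what the standard benchmark layouts contain after
  conversion).
* No pretrained weights, no test-time augmentation, no learning-rate
  schedules; the checkpoint keeps the best validation mean dice, which is
  the only model-selection mechanism.
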