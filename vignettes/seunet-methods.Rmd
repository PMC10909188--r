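---
title: "Methods: nested-U segmentation with SE attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nested-U segmentation with SE attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(seunet)
```

## The model

`seunet` implements the two-level nested-U family of encoder–decoder
segmentation networks for liver occupying lesion segmentation in abdominal
CT. The building unit is the *residual U-block* (RSU-L): an input
convolution maps `in_ch` to `out_ch` channels and feeds a residual branch,
while a small U-shaped sub-network — L encoder levels of
convolution + batch normalization + ReLU with 2×2 max pooling between them,
a dilated bottom convolution, and a mirrored decoder on concatenated
skip/upsampled features — extracts multi-scale context. Its output is added
to the residual branch, so every block preserves spatial size. The dilated
variant RSU-4F replaces all resampling with dilated convolutions (encoder
dilations 1, 2, 4, bottom 8, mirrored decoder), so it works at any
resolution, including odd sizes.

Eleven such blocks form the outer U: six encoder stages
(RSU-7(3,32,64), RSU-6(64,32,128), RSU-5(128,64,256), RSU-4(256,128,512),
and two RSU-4F(512,256,512)) with pooling between them, and five decoder
stages (RSU-4F(1024,256,512), RSU-4(1024,128,256), RSU-5(512,64,128),
RSU-6(256,32,64), RSU-7(128,16,64)) each fed by the upsampled deeper
feature concatenated with the encoder skip. One 3×3 side convolution per
decoder stage plus one from the deepest encoder stage produce six
class-logit maps, each bilinearly upsampled to the input size; a 1×1
fusion convolution over their concatenation yields the final prediction.

The SE variant places a *squeeze-and-excitation* unit on the residual
branch of each of the eight non-dilated stages: global average pooling
produces per-channel descriptors, a bottlenecked pair of affine maps with
ReLU then logistic activation produces gates in (0, 1), and the branch
becomes `gates ⊙ x + x`. The SE unit sits on the input-convolution output
that feeds the final residual addition — the one reading under which
"after the first convolutional block" and "at the position of the residual
connection" coincide.

## The SE weight layout and the parameter audit

The published complexity accounting reports a *constant* overhead of 148
parameters per SE unit although the recalibrated widths range from 64 to
512 channels. A conventional per-channel SE cannot be constant across
widths; the only layout consistent with the printed numbers is a
*shared-group* SE: one `(16 → 4 → 16)` affine pair (with biases;
16·4+4 + 4·16+16 = 148 parameters) applied to every consecutive group of
16 channels with shared weights. `se_config()` defaults to this layout and
also offers the conventional `per_channel` mode.

A second accounting subtlety: the printed totals (44,052,518 for the
baseline and 44,053,702 for the SE variant) equal the trainable parameters
of the two-class softmax head *plus* the batch-norm running means and
variances (2 × 14,400 BN channels = 28,800). Neither candidate head
reproduces the totals on trainable parameters alone (one-class sigmoid
head: 44,009,869; two-class softmax head: 44,023,718). `count_parameters()`
therefore reports `total_params` under the printed convention (trainable +
BN moments) alongside `total_trainable`, and cross-checks the enumerated
counts against a brute-force traversal of a built model. The reported
per-SE-block overhead of "148 FLOPs and 144 Params" appears to swap the two
quantities: only 148 parameters per block reconciles with the totals
(8 × 148 = 1,184, the difference between the two variants), so 148
params/block is treated as authoritative. FLOP counts are reported for
information only (`total_mult_adds`); they are convention-dependent and
never used as an acceptance quantity.

## Losses

Training minimises a mixture of pixel-wise cross-entropy over the softmax
class probabilities and a soft Sørensen–Dice loss on the foreground
probability, with weights 0.7 and 0.3. As printed, the source's Dice
expressions omit the conventional factor 2 — under which a perfect match
would score 1/2, contradicting reported Dice coefficients near 0.95 — so
the standard definition `2|A∩B|/(|A|+|B|)` is implemented, and
`dice_loss(hard masks) = 1 − dice_coeff(same masks)` holds across modules.
Numerical guards: Dice smoothing ε = 1e-6 (also defines perfect agreement
on jointly empty masks), log clamping at 1e-12 in the entropies.

Whether the loss was applied to the side outputs is not specified by the
source; the nested-U family convention is deep supervision, so
`supervised_loss()` sums the selected loss equally over the fused and six
side outputs by default, with a `fused_only` switch exposing the other
reading. Evaluation always uses the fused output. A BCE arm and single-loss
arms (`ce`, `dice`) are available as configuration keys so the four loss
ablation arms are expressible with the same trainer.

## Metrics

All four metrics derive from per-class pixel tallies accumulated globally
over the evaluation split (the area-based confusion formulation), not from
per-image averages; a per-image diagnostic is possible by evaluating slices
individually. IoU and Dice use the lesion class; accuracy is overall pixel
accuracy (the standard reading of the quoted area definitions, adopted
where the formulation leaves mean-class accuracy open); Cohen's kappa uses
`(Acc − P_e)/(1 − P_e)` with `P_e = Σ_c pred_c · label_c / total²`. Edge
conventions, tested explicitly: jointly empty foreground scores IoU = Dice
= 1; a constant single-class prediction has kappa 0 (or 1 when the truth
is the same constant); `dice = 2·iou/(1 + iou)` holds exactly for every
accumulated state. Per-pixel argmax resolves ties toward background.

## Training procedure

The optimizer is momentum SGD with the Nesterov flag (momentum 0.9 and
weight decay 0, both configurable; the source states neither), batch
size 4, 9,000 iterations with a checkpoint every 900. "Training runs" is
read as optimizer iterations, consistent with the per-900 checkpoint
cadence. The learning rate follows cosine annealing
`η_min + ½(η_max − η_min)(1 + cos(π t_cur / T_i))` with η_max = 0.0015,
η_min = 0 and T_i = 5400. Because the total iteration count (9,000)
exceeds one cycle (5,400), the cycle index is read as warm restarts
(`restart = TRUE`, `t_cur = t mod T_i`); a clamped mode holds η_min after
one cycle. Checkpoint selection for evaluation is the last checkpoint.
Batch normalization uses batch statistics during training (momentum 0.1
running updates) and running statistics at evaluation, which also makes
evaluation deterministic. No data augmentation is applied (none is
described for the original experiments).

## Preprocessing

NIfTI volumes are reduced to the axial slice range containing labelled
voxels, then exported slice by slice as 8-bit grayscale PNG pairs. Under
the LiTS convention only the tumor label is retained
(2 → 1, {0, 1} → 0); under the PUFH binary convention any positive label
is lesion. Whether slices between the liver extent and the lesion extent
were kept is ambiguous in the source description; the convention parameter
exposes both readings (the labelled range is whatever the chosen
convention's labels span). HU values are windowed to [−200, 300] by
default — a soft-tissue-inclusive window; the source specifies none, so it
is configurable and recorded in the export manifest — rescaled linearly to
0..255 and rounded half-up; images resize bilinearly, masks by nearest
neighbour. The 8:1:1 train/val/test split is performed at *volume* level
(slice-level splitting would leak adjacent, nearly identical slices across
splits), shuffled under a seed, floors allocated to val/test and the
remainder to train. Grayscale slices are replicated to three channels at
load time to match the three-channel input convolution pinned by the
parameter audit.

## The synthetic phantom

Real data for this task are a private clinical dataset and a GPU-scale
external challenge dataset, so the package ships a generator instead of
fixtures: an ellipsoidal bright "liver" (60 ± 10 HU) on an air background
(−1000 HU) containing disjoint darker spherical "lesions" (0 ± 15 HU),
with 5 HU Gaussian noise everywhere — intensities chosen to mimic
contrast-CT soft-tissue ranges. Lesion spheres are sampled strictly inside
the liver and pairwise disjoint, so connected components of the lesion
label equal the lesion count. Labels are emitted in both conventions.
Everything is a deterministic function of the spec, including its seed.

What the phantom does *not* emulate: anatomical shape variability,
multiple organs, partial-volume effects, scanner reconstruction texture,
or lesion shape irregularity (lesions are spheres; shape does not affect
any structural or analytic property the tests check). Passing tests on the
phantom therefore demonstrate that the pipeline, losses, metrics and
optimizer behave as specified — not that the full-size network reaches any
particular accuracy on clinical CT.

## Problem sizes and the smoke configuration

The default phantom is 96 × 96 × 24 (a 512 × 512 phantom is available for
integration work). The learning smoke test trains `smoke_config()` — the
same 11-stage topology with 8 residual / 4 internal channels and
per-channel SE with bottleneck 2 — on the 8 phantom slices with the
largest lesion cross-sections at 96 × 96 for 200 iterations, one cosine
cycle (`T_i = 200`, clamped). The smoke run uses η_max = 0.01: the
full-scale rate of 0.0015 is tuned to a 44M-parameter network and 9,000
iterations, and a 200-iteration budget on a 50k-parameter network needs a
proportionally faster schedule to leave random initialisation. The smoke
criteria — training loss at least halved, train-set Dice ≥ 0.8 — were
fixed from five pre-runs of this configuration under different seeds.

## Known limitations

- CPU-only dense linear algebra: full-size (44M-parameter) training is out
  of reach; the full configuration is exercised structurally (construction,
  forward shapes, parameter audit) and the training loop at smoke scale.
- Bilinear upsampling uses half-pixel-centre sampling without corner
  alignment, and pooling uses ceiling semantics; other frameworks'
  conventions differ in edge handling, so weight-level transplantation
  from other implementations is not bit-exact.
- The headline clinical metrics of the original experiments require the
  private clinical dataset or GPU-scale training on the external challenge
  data and are not reproduced here.
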