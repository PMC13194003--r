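---
title: "HPRNet: model, pruning and evaluation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HPRNet: model, pruning and evaluation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hprnet)
```

## The classification problem

Heartbeat-level arrhythmia classification assigns each annotated beat of a
single-lead ECG to one of the AAMI classes: N (normal, bundle-branch block
and escape beats), S (supraventricular ectopic), V (ventricular ectopic),
F (fusion) and Q (unknown/paced). Beats are fixed windows of 128 native
samples centred on the annotated R peak — at 360 Hz roughly 0.36 s, enough
to cover the P wave, QRS complex and most of the T wave. Each beat is
z-scored, so absolute amplitude calibration is irrelevant downstream.

## The network

`hpr_config()` describes a hierarchical pyramidal residual network for
inputs $x \in \mathbb{R}^{1 \times L}$ with $L = 128$:

* **Front end** — one temporal convolution (kernel 17, stride 1, padding 8,
  no bias) taking the single lead to 32 channels, followed by batch
  normalisation and ReLU.
* **Backbone** — nine residual layers (ResLayers). ResLayer $l$ is a cascade
  of $N_l$ residual extraction blocks (REBs); the default schedule is
  $N = [3,4,4,4,4,4,4,4,3]$ with channel widths
  $32 \to 64 \to 64 \to 128 \to 128 \to 256 \to 256 \to 512 \to 512 \to 1024$
  and stride 2 at every transition after the first. Temporal length thus
  shrinks $128, 64, 32, \dots, 1$ while channels grow — a pyramid that
  trades temporal resolution for representational width.
* **REB** — pre-activation main branch
  $\mathrm{Conv}(\mathrm{ReLU}(\mathrm{BN}(\cdot)))$ applied twice with
  kernel 17 and padding 8 (no conv biases), summed with a skip branch. The
  first REB of each ResLayer carries the stride and the channel change; its
  skip is a strided $1 \times 1$ convolution followed by a shape-preserving
  max pool (kernel 3, stride 1, padding 1). The remaining REBs are
  stride-1, same-width, and their skip is the max pool alone — a
  parameter-free nonlinear shortcut that passes locally dominant responses.
  Kernel 17 at 360 Hz spans about 47 ms, the temporal scale of a QRS
  complex.
* **Head** — dropout ($p = 0.5$), global average pooling over time, one
  fully connected layer with bias, softmax.

The forward and backward passes are implemented as im2col gathers plus BLAS
matrix products, with the gather/scatter and the fused Adam update in C++.
No external deep-learning runtime is involved; gradients are verified
against numerical differentiation in the test suite.

### Two head sizes

The *complexity-reference* configuration (`hpr_config()` defaults) uses an
8-way output layer, matching the eight representative beat types of the
source databases (normal, paced, LBBB, RBBB, atrial premature, ventricular
premature, flutter, escape); all parameter accounting in the test suite and
the acceptance script uses this head. Classification tasks construct their
own head — 4 classes for the AAMI task, 2 or 3 for the binary and
three-class variants — by passing `num_classes`.

## Complexity accounting

`count_parameters()` is a closed form over the tensor table
(`model_tensor_table()`): convolutions contribute
$c_{in} c_{out} k$ weights (no biases), batch-norm layers $2c$ (scale and
shift), the fully connected layer $c \cdot C + C$. The enumeration oracle
(`nonzero_count()` on a built model) must agree exactly; a property test
checks this over randomised architectures. `count_flops()` counts
$2\,c_{in} c_{out} k\,L_{out}$ per convolution (one multiply and one add per
MAC) and excludes batch norm, pooling and activations; FLOP conventions
differ enough across tools that cross-implementation comparisons should be
treated as order-of-magnitude only.

## Multi-level pruning (MLPO)

Unstructured L1-magnitude pruning is applied **per tensor**: with ratio $r$,
the $\mathrm{round}(r \cdot \mathrm{numel})$ smallest-magnitude entries of
each selected weight tensor are set to zero. Two scopes exist and compose:

* **network level** — the front convolution weight and the fully connected
  weight;
* **block level** — every REB convolution weight: both main-branch convs
  and the first-REB $1 \times 1$ skip convs.

`"mlpo"` is their union. Batch-norm parameters and biases are never pruned.
Per-tensor proportional pruning makes the remaining-parameter count affine
in $r$ (up to per-tensor rounding), which is exactly the behaviour the
accounting tests pin down. Ties in magnitude are broken by flat index
(lower index pruned first) so results are bit-reproducible. Pruning happens
once, at model construction; training then proceeds with the masks
enforced — masked gradients are zeroed and masked weights re-zeroed after
every optimizer step — rather than with a separate prune-then-fine-tune
schedule. The model size reported for a pruned network is the number of
parameters not fixed at zero by a mask; parameters that merely happen to
hold zero (for example freshly initialised biases) still count.

## Training and evaluation protocol

Training uses Adam (initial rate $10^{-3}$), batch size 128, at most 30
epochs, unweighted categorical cross-entropy, and a reduce-on-plateau
schedule: the rate is halved (floor $10^{-5}$) after `patience + 1 = 4`
consecutive epochs without validation-loss improvement. The returned model
is the best-validation-loss checkpoint, which decouples results from
final-epoch noise. Class imbalance is deliberately left uncorrected; the
per-class metrics make its consequences visible instead.

Cross-validation is stratified at the **beat** level (an intra-patient
protocol: beats from one recording can appear in both training and test
folds; inter-patient generalisation is out of scope). Within each round,
10% of the training beats (stratified, seeded) are carved out as the
validation set driving the schedule and model selection — the held-out test
fold is never touched during training.

Metrics follow the one-vs-rest definitions: per class,
$P = TP/(TP+FP)$, $R = TP/(TP+FN)$, $F1 = 2PR/(P+R)$; overall accuracy is
the diagonal fraction of the confusion table (which coincides with the
pooled one-vs-rest accuracy in the binary case; for $C$ classes the pooled
form equals $1 - 2(1-\mathrm{acc})/C$). Macro scores are unweighted class
means, and
the cross-fold summary is the unweighted mean of per-fold metrics. Values
are stored at full precision and rounded to two decimals only for display.
A class absent from a test fold has undefined recall; it is reported as 0
with a warning rather than silently dropped.

## Synthetic beats

`synth_dataset()` builds each beat as a sum of five Gaussian bumps
(P, Q, R, S, T) on the unit interval, plus a baseline-wander sinusoid with
random phase and white noise. Class variants follow the usual clinical
sketch: S-like beats lack the P wave and have a narrow QRS; V-like beats
have a wide (3x), high-amplitude QRS and an inverted T wave; F is the
average of the N and V templates. Defaults — noise SD 0.05 of the R
amplitude, wander amplitude 0.1 at 0.5 Hz — keep the four classes
template-separable (a max-correlation classifier recovers ~99.9% of labels
at noise 0.1), which is the point: the generator exists to make every
pipeline stage testable end to end, with known ground truth, offline.

What it does **not** emulate: real morphological variability within a
class, rhythm context (RR intervals, compensatory pauses), inter-patient
differences, electrode artefacts, or pathological ST/T changes. Passing on
synthetic data therefore demonstrates that the machinery — segmentation,
training, pruning, saliency — is correct, not that clinical-grade accuracy
transfers to real recordings.

## Wavelet denoising

The optional preprocessing stage decomposes each record (before
segmentation, so beat windows see consistent context) with a sym8 discrete
wavelet transform, five levels, half-point symmetric boundary extension.
Detail coefficients are soft-thresholded at the universal threshold
$\sigma \sqrt{2 \ln N}$ with $\sigma$ estimated as
$\mathrm{median}(|d_1|)/0.6745$ from the finest level, then the signal is
reconstructed at its original length. The transform is implemented directly
(the filter coefficients are published constants) and was validated
coefficient-for-coefficient against an independent DWT implementation
before its regression values were frozen. The default pipeline does not
denoise; the flag exists to measure the effect of denoising, which for this
architecture is marginal.

## Grad-CAM for 1D signals

Saliency maps are computed from the gradient of the **pre-softmax logit**
of the target class with respect to a chosen ResLayer's output activations:
channel weights are the temporal mean of that gradient, the map is the
ReLU of the weighted channel sum, linearly interpolated back to the beat
length and min-max normalised per map (the figures of interest are
relative heat per depth; absolute scales are not comparable across
layers). A map that is identically zero before normalisation stays zero.
Probing `ResLayer0`, `ResLayer3` and `ResLayer5` gives the
shallow/intermediate/deep views of what the backbone attends to.

## Numerical choices and degenerate inputs

* Pruned amount per tensor is `round(r * numel)` with IEEE
  round-half-to-even; all default tensor sizes are even, so no half-way
  cases arise at ratios in tenths.
* A constant beat z-scores to all zeros (no NaNs); max-pool gradient ties
  route to the leftmost position; pruning ties break by flat index.
* Batch-norm uses $\epsilon = 10^{-5}$, momentum 0.1, and falls back to
  running statistics for singleton batches.
* Weight initialisation is He-scaled Gaussian; every stochastic step
  (initialisation, shuffling, dropout, generator noise) is governed by
  explicit seeds, so runs are bit-reproducible on a fixed BLAS.
* 0-based sample indices and half-open windows are used throughout the
  WFDB layer; R-facing containers use 1-based row indices and factors.

## Problem sizes in the test suite

The suite trains small-width models (channels 8–16) on a few hundred
synthetic beats for the learning-dynamics tests, and one slim full-width
model (one REB per ResLayer, channels 32–1024, ~48.5M parameters) on an
800-beat four-class task, which reaches >95% validation accuracy within a
handful of epochs in a few minutes on one CPU. Full-scale accounting
(190.7M parameters) is exercised through the closed form plus one built
model; the acceptance script additionally builds and prunes every
configuration it reports on.

## Known limitations

* Intra-patient evaluation only; no patient-wise fold option yet.
* Unweighted loss; no class-balancing or augmentation.
* WFDB support covers headers, signal formats 212/16 and MIT-format beat
  annotations — the subset the target databases use — not the full format
  zoo.
* Only the sym8 wavelet ships; the denoising stage is deliberately minimal.
* Double precision on CPU only; no GPU path.
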