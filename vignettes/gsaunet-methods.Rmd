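---
title: "Gated skip-connections and adaptive upsampling for retinal vessel segmentation: methods and design notes"
author: "gsaunet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Segmenting the retinal vasculature in fundus photographs is a pixelwise
binary classification task: every pixel inside the camera's circular field
of view (FOV) is either vessel or background. `gsaunet` implements an
encoder--decoder convolutional network of the U-Net family with two
specific mechanisms on the decoding path.

**Gated skip-connection (GS).** A plain U-Net skip copies the encoder
feature $E_t$ straight into the decoder, noise included. The gated variant
computes an attention map from both sides of the skip,

$$\alpha_t = \sigma\!\left(\mathrm{Conv}_{1\times 1}(E_t \oplus D_t)\right),$$

where $\oplus$ is channel concatenation and $\sigma$ the logistic
function, and transmits

$$Y = (E_t \odot \alpha_t + E_t) \;\oplus\; D_t .$$

The product $E_t \odot \alpha_t$ gates the encoder information; adding
$E_t$ back preserves a residual path so the gate can only *emphasise*,
never completely sever, the skip; the concatenation with $D_t$ hands both
streams to the next convolution block. Written this way every operation is
shape-consistent: the gate emits one attention channel per encoder channel
(`gate_channels = "per_channel"`), so the elementwise product needs no
broadcasting rule. A single broadcast attention channel is available as
`gate_channels = "single"` for ablations.

**Adaptive upsampling (AU).** The decoder must double the spatial
resolution four times. Bilinear interpolation is parameter-free but
data-independent; transposed convolution is learnable but adds parameters
and checkerboard-prone arithmetic. Adaptive upsampling takes a middle
road: a convolution expands the channel count by a factor $r^2$, and a
*periodic rearrangement* (depth-to-space, sub-pixel shuffle) relocates
each group of $r \times r$ channels into an $r$-times-larger spatial grid:

$$\mathrm{out}[y, x, c] = \mathrm{mid}\!\left[\lfloor y/r\rfloor,
\lfloor x/r\rfloor,\; c\,r^2 + (y \bmod r)\, r + (x \bmod r)\right].$$

The rearrangement moves values without arithmetic, adds zero parameters,
and is exactly inverted by `pixel_unshuffle()`; all learning lives in the
preceding convolution.

**Architecture.** Four encoder stages (widths $w, 2w, 4w, 8w$ for
`base_width` $w$), each a block of two $3\times3$ convolutions with batch
normalization; stride-2 $3\times3$ convolutions downsample between stages
(chosen over pooling to reduce information loss); a $16w$-channel bridge;
four decoder stages of upsample → gated skip → convolution block; and a
$1\times1$ sigmoid head. The input image is additionally bilinearly
resized to 1/2, 1/4 and 1/8 scale, embedded by a $3\times3$ convolution,
and concatenated into encoder stages 2--4 ("multiscale input"), so a
$48\times48$ patch contributes $24\times24$, $12\times12$ and $6\times6$
pyramids. Input sides must divide by $2^4 = 16$.

## Deliberate readings of under-specified details

Several points of the architecture admit more than one reading; the
package fixes them as follows and exposes switches where reasonable.

* **The gated-skip formula.** Read literally, "$C_t + E_t \oplus D_t$" is
  shape-inconsistent. We read "+" as the residual skip (add $E_t$ to the
  gated product) and "$\oplus$" as the channel concatenation with $D_t$,
  the only composition in which every term has a defined shape and both a
  skip-connection and a channelwise concatenation occur.
* **Block activation order.** The default `norm_order = "deferred"`
  follows the stated sequence literally — two conv+norm pairs with a
  single ReLU closing the block; `"conventional"` inserts the usual
  middle ReLU.
* **Subwindow factor $r$.** The decoder doubles resolution per stage, so
  the stage-wise default is $r = 2$ at each of the four stages. Factors 4
  and 6 are supported by `pixel_shuffle()`/`adaptive_upsample()` for
  single-shot upsampling experiments, but the standard decoder requires
  $r = 2$.
* **Upsampling parameter budgets.** The AU expansion convolution is
  $3\times3$ and bias-free (the shuffle that follows is parameter-free);
  the transposed-convolution ablation uses $k = 6$, $s = 2$, $p = 2$
  (exact doubling by the size relation $o = s(i-1) - 2p + k$) and carries
  the same weight count plus output biases; the bilinear ablation is the
  interpolation preceded by a $3\times3$ channel-reduction convolution.
  At any fixed width this yields the strict ordering
  *bilinear < adaptive ≤ deconv* in learnable parameters, mirroring the
  near-tie between AU and deconvolution footprints with bilinear well
  below both.
* **Bilinear convention.** Corner-aligned sampling (first/last pixels map
  to first/last). Resizing to the input size is then exactly the
  identity, and each output pixel is a convex, weights-sum-to-one
  combination of its four nearest sources — the property the oracle tests
  check.
* **Convolution biases.** Convolutions directly followed by batch
  normalization carry no bias: the normalization removes the channel mean,
  so such a bias receives an exactly zero gradient and would be dead
  weight. For the same reason the multiscale image embeddings are
  conv--norm--ReLU: a bias-free ReLU embedding fed directly by a
  positive-valued image leaves channels whose kernels sum negative
  permanently dead.
* **AU initialization.** The expansion convolution is ICNR-initialized:
  the $r^2$ subkernels of each output channel start identical, so the
  initial rearranged output is a smooth nearest-neighbor-like upsample
  instead of checkerboard noise — the standard remedy for sub-pixel
  convolution artifacts, and material in short training runs.

## Training protocol

Training is patch-based: `sample_patches()` draws a fixed number of
$48\times48$ patches per image (10,480 at full protocol scale), centers
uniform with replacement over positions whose center pixel lies in the
FOV. The loss is the mean binary cross-entropy over pixels, with
predictions clipped to $[10^{-7}, 1-10^{-7}]$ for a finite value; the
gradient is taken through the logits, $\partial L/\partial z = (p - y)/M$.
The optimizer is Adam with first-moment decay $\beta_1 = 0.9$ (the
protocol's stated exponential decay rate; the second moment keeps its
conventional 0.999), initial learning rate $10^{-3}$, weight decay
$5\times10^{-4}$ added to the gradient, and *step decay*: the learning
rate is multiplied by $1 - 0.01$ every `lr_step` epochs (interval
configurable; every epoch by default — the protocol names the coefficient
but not the interval).

At inference, full images are covered by overlapping $48\times48$ tiles
(stride 24 by default), predictions averaged per pixel by overlap count;
reflect-padding covers images smaller than one tile. Tiling is this
package's addition: a patch-trained network needs *some* full-image
procedure, and uniform-weight tile averaging is the simplest one whose
weights provably sum to one at every pixel. Images whose sides divide by
16 can also be predicted in a single convolutional pass.

## Evaluation

`confusion()` tallies TP/FP/TN/FN over FOV pixels only — the DRIVE-family
convention (`fov_restrict = FALSE` disables it); the binarization
threshold defaults to 0.5. `seg_metrics()` applies the standard ratios
(accuracy, sensitivity, specificity, precision, and F-measure as the
harmonic mean of precision and sensitivity); any zero denominator yields a
flagged `NA`, never a silent zero. `roc_pr()` sweeps the unique score
values, so tied scores form single sweep points and the trapezoidal
ROC area equals the Mann–Whitney rank statistic (ties counted half) — an
identity the tests assert against an all-pairs oracle. Multi-image
reports average per-image metrics unweighted, which is also the
leave-one-out aggregation with one image per fold.

## The synthetic phantom generator

Public fundus datasets cannot ship inside a package, so `synthvessel`
generates phantoms that emulate the *structure* of the green channel of a
fundus photograph: branching vessel trees drawn as random walks of
tapering width (1–4 px by default, covering the thin-vessel regime), dark
on a brighter background; a radial illumination falloff; additive and
low-pass-filtered Gaussian noise; a circular FOV mask with a dark
exterior; 8-bit quantization so disk round trips are bit-exact. Defaults
were fixed once so that the vessel fraction inside the FOV lands near
0.10–0.15 (measured 0.10–0.16 over seeds at both 565×584 and 128×128),
within the plausible range for fundus vasculature. The generator is
seed-deterministic and leaves the caller's RNG state untouched.

What the phantoms do *not* emulate: pathology (lesions, exudates,
hemorrhages), the optic disc and macula, camera vignetting asymmetries,
JPEG artifacts, inter-annotator ambiguity, and the low-contrast capillary
end of real vasculature. Passing desk-scale tests therefore demonstrates
that the implementation *trains and segments correctly*, not that it
reproduces benchmark accuracy on DRIVE/CHASE/STARE — that would require
the real images and full-protocol training (200 epochs × 10,480 patches ×
20 images on GPU hardware), which is out of scope here; the full-protocol
hyperparameters ship in `configs/fullscale.yaml` for users with the data and
hardware.

## Numerical engineering

Two implementations of the network exist by design. The *reference path*
(`R/layers.R`, double precision) defines the semantics: it is the one the
operator oracles, finite-difference gradient checks (central differences
at $\varepsilon = 10^{-7}$, where estimates are clean of ReLU-kink
contamination) and exactness tests run against. The *native engine*
(`src/engine.cpp`) holds parameters, Adam state and all activation
workspaces in C++ between steps and runs convolutions in single precision
via im2col + GEMM (per-sample-chunked so buffers stay cache-sized); a test
asserts both paths agree on loss, every gradient and the post-training
forward pass. Training is deterministic for a fixed seed on a given
machine; exact bit-reproducibility across BLAS builds is not promised.
Batch normalization uses $\varepsilon = 10^{-5}$ and running-statistic
momentum 0.1 (unbiased variance in the running estimate).

Desk-scale problem sizes used by the tests and the acceptance script —
base width 16, ten 128×128 training phantoms, 200 patches per image,
batch 32, two epochs, three held-out phantoms — are the package's chosen
single-CPU profile (`configs/desk.yaml`); they were sized so a full
training run completes in minutes while still reaching high desk-scale
accuracy, and the learning-trend test uses an even smaller corpus.

## Known limitations

* No data augmentation beyond random patch location (none is part of the
  protocol).
* Full-protocol patch counts (10,480 × 20 images) are materialized in
  memory by `train_network()`; a streaming sampler would be needed well
  beyond desk scale.
* The gating-versus-baseline advantage at desk scale is a small effect
  under training noise (seed-to-seed variation of the F-measure is of the
  same order as the gap), which is why the corresponding check is framed
  over multiple seeds.
* GIF masks of the public datasets are not readable here; PNG layouts
  (and estimated FOVs for mask-less STARE-style data) are supported.
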