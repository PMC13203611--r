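---
title: "Dual-frequency free-fluid detection: models, phantoms and accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-frequency free-fluid detection: models, phantoms and accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

sonolite implements a lightweight anchor-free detector for free fluid in
FAST (Focused Assessment with Sonography for Trauma) B-mode frames. Free
fluid — blood pooling in body cavities during active haemorrhage — reads
as irregular anechoic or hypoechoic pockets with continuous boundaries,
usually surrounded by speckled parenchyma. Its signature splits cleanly
in the spatial-frequency domain: the overall echo-intensity distribution
and region continuity live in the low frequencies, boundary sharpness and
parenchymal texture in the high frequencies. The architecture exploits
that structure to cut computation while keeping the detail stream intact.

## The model

The detector is a compact YOLOX-family network (stem + four CSP stages,
three pyramid exports C3/C4/C5 at strides 8/16/32, a decoupled
single-class head) with two structural replacements.

**Dual-stream fusion (DSF) backbone.** After the stem, channels split
into a high-frequency stream at full resolution and a low-frequency
stream at half resolution; the low fraction is `alpha` (default 0.5,
low-group channel count `round(alpha * C)`, ties up). Every stage
convolution is an octave convolution: four weight paths H→H, H→L, L→H,
L→L whose weights always sum to exactly the plain convolution's count,
so the parameter count is invariant to `alpha` while FLOPs fall as
`alpha` grows (the low stream works on quarter-area maps). Inter-stream
resolution changes are parameter-free: 2x2 average pooling before the
H→L convolution, nearest-neighbour upsampling after the L→H convolution.
A dedicated *cross-fusion module* — a full octave convolution with
per-path normalisation — sits after every stage to exchange information
between the streams; it uses 3x3 kernels after the first three stages and
a 1x1 kernel after the deepest (widest) stage. The cross-fusion modules
after stages four and five merge the streams (`alpha_out = 0`), so C4 and
C5 are single-stream; C3 is exported by concatenating the high stream
with the upsampled low stream. The stream is re-split at the entry of the
next stage. The "no-fusion" ablation keeps the dual streams but drops the
inter-frequency paths and the cross-fusion modules.

**Global fusion feedback (GFF) neck.** Instead of the bidirectional
PANet-style neck, a single global fusion (GF) feature is built once per
image: C5 is upsampled and concatenated with C4; a pyramid pooling module
(adaptive average pooling at output sizes 1, 2, 3 and 6, each followed by
a 1x1 projection and nearest upsampling) summarises that context at
several receptive fields; the branches are concatenated and fused by a
1x1 convolution, upsampled to stride 8, passed through one more 1x1
convolution, and added to C3. The GF map is fed back bottom-up: P3 is the
GF map itself; P4 and P5 concatenate the (average-pool downsampled) GF
map with C4/C5 and fuse with a 1x1 convolution. There is no stepwise
C5→C4→C3 chain, and the pooling stages add no parameters.

**Head, assignment and loss.** The decoupled head predicts, per grid
cell, a class logit, an objectness logit and four box values; decoding
is anchor-free (centre `(j + dx) s`, size `exp(dw) s`). Positives are
chosen by SimOTA: candidates are cells whose centres fall inside a truth
box or within 2.5 strides of its centre; the matching cost is
`Lcls + 3 Lreg` with `Lcls` the binary cross-entropy of the joint
confidence and `Lreg = -log(IoU)`; each truth takes its `k` cheapest
candidates with `k = max(1, floor(sum of its top-10 candidate IoUs))`; a
cell claimed twice keeps its cheapest match, and a truth stripped of all
picks falls back to its cheapest unclaimed candidate, so every truth
with a candidate keeps a positive. The training objective is
`5 l_reg + l_cls + l_conf` (IoU loss on positives, cross-entropy on
positive class logits, cross-entropy on all objectness logits), all
normalised by the number of positives — the weighted positive/negative
balance of this detector family.

## Variants and published complexity

Two scales are provided: `tiny` (depth 0.33, width 0.375) and `nano`
(depth 0.33, width 0.25, depthwise-separable convolutions, including in
the cross-fusion paths). The `*-lite` variants combine the DSF backbone
and GFF neck.

```{r}
library(sonolite)
profile_model(model_config("tiny-lite"), calibrate_convention())
```

The analytic profiler counts parameters exactly and FLOPs per layer
(`C_in C_out k^2 H W / groups` multiply-accumulates; pooling and
interpolation are free). The counting convention — input 512x512, one
operation per MAC, plus two operations per normalised element — is fixed
by a calibration search over input sizes {416, 512, 640} and MAC factors
{1, 2} against the published complexity of the two unmodified baselines
(4.845 G and 0.790 G); the elementwise term is required, since without it
the nano baseline cannot be matched within 1% at any grid point. Under
this frozen convention the package reproduces the published tiny/nano
baselines, the backbone-only and neck-only ablations and the tiny-Lite
FLOPs within 1%, with parameters integer-exact where the architecture is
pinned.

Three published figures are *not* exactly reproducible from the
published material, and the package deliberately leaves the deviations in
place rather than fitting unprincipled layer combinations:

* tiny-Lite parameters: 4.532 M here vs 4.592 M published (-1.3%). Every
  architecturally consistent neck layout we enumerated leaves a ~61k-parameter gap
  while our layout matches the published neck FLOPs to 0.003%.
* nano-Lite: 0.868 M / 0.516 G here vs 0.820 M / 0.554 G published. The
  published pair implies a mixture of depthwise and full convolutions in
  the nano cross-fusion that cannot be recovered from the published
  numbers; we keep the family rule (depthwise everywhere in nano).
* the `alpha = 0.2` sweep point: 4.376 G here vs 4.692 G published
  (-7%). The published sweep has a non-smooth slope change around
  `alpha = 0.5` that no octave cost model of this architecture family can
  produce: the whole network's MAC budget bounds the attainable slope.

The invariances that define the design — parameter count identical across
`alpha`, FLOPs strictly decreasing in `alpha` — hold throughout and are
asserted in the test suite.

## The runtime engine

The package ships its own CPU engine: a float32 static-graph runtime
(im2col + BLAS `sgemm` convolutions, fused normalisation + SiLU kernels,
two grow-only arenas for forward activations and gradients so an
iteration performs no R-level allocation for feature maps). Weights and
their gradients are R double arrays, so the SGD optimiser and
serialisation are double-precision; all accumulation orders are fixed,
making runs bit-reproducible for fixed seeds. Backward passes are
verified against central finite differences (normalised directional
derivatives, agreement to better than 1% — the float32 noise floor).

Normalisation is affine channel normalisation with statistics computed
per sample over spatial positions, at training and at inference
(instance-normalisation semantics). This choice is batch-size independent
and deterministic; switching to accumulated averages at inference is
numerically wrong for per-sample statistics — deviations compound across
a hundred layers. The exception is layers on very small maps (the pooled
1x1–3x3 context branches of the PPM, where per-sample statistics over
<16 positions are degenerate): these normalise with accumulated running
statistics in both modes, updated with momentum 0.05, and their backward
pass treats the statistics as constants. Parameter counts (2 scale/shift
per channel) match batch normalisation, so profiling is unaffected.

## The phantom generator

`generate_phantoms()` emulates the structure of an in-vivo free-fluid
screening dataset: a smooth parenchymal reflectivity field with depth
attenuation, two to four bright curvilinear tissue bands, one to three
star-convex hypoechoic pockets per positive frame (polar outlines with
smoothed random radii; boundaries softened by a short blur; tight
axis-aligned boxes), mild posterior enhancement beneath each pocket,
multiplicative Rayleigh speckle smoothed by a short-range kernel, and
log compression to 8 bit. The default parenchyma-to-fluid reflectivity
ratio is 12, rendering pockets nearly anechoic after log compression —
the appearance of free fluid rather than of a mild hypoechoic lesion.
A `p_empty` fraction of frames (default 0.15, a free choice — the source
publication does not print its negative-frame rate) carries no target, as
in the source data where probe movement lost the fluid from view.
Datasets are pure functions of (configuration, seed).

What the phantoms do *not* model: attenuation shadows, refraction and
mirror artefacts, anatomy-specific organ interfaces, probe-dependent
point-spread anisotropy, and inter-subject variability. Passing the
training checks on phantoms therefore demonstrates that the optimisation
and detection machinery works end to end, not that the model would reach
the published accuracy on in-vivo frames.

## Training protocol and desk scale

Training follows the published recipe: SGD with momentum 0.9, weight
decay 5e-4, base rate 1e-2 with a quadratic warm-up over 5 epochs,
dropped to 1e-3 and 1e-4 at the 60% and 85% marks; batch 16; Mosaic,
MixUp and horizontal-only flips (vertical flips would break the physical
probe-at-top orientation), with Mosaic/MixUp disabled for the final 15%
of epochs. The full-scale recipe (640x640, 300 epochs) is available
through `train_config()`, but the shipped checks run at the package's
desk scale, chosen so the whole suite completes on one CPU:

* gradient and one-step checks at 96 px;
* the overfit smoke at 160 px: 8 phantoms, 120 epochs, loss must fall
  by at least 10x;
* the end-to-end check at 320 px: nano-Lite trained for 24 epochs
  (the largest schedule the suite budget allows; the full-scale recipe
  uses far more) on 100 phantoms must reach at least 80% recall at
  IoU 0.5 on 40 held-out phantoms, with fixed seeds 101/5;
* cross-validation machinery exercised with 1-epoch folds at 96 px.

The operating point for precision/recall/F1 is a 0.5 confidence
threshold (the source publication does not state its own); evaluation
uses greedy score-ordered matching and the COCO dialect of average
precision (101-point interpolation, thresholds 0.50–0.95). Frames are
the cross-validation unit; when consecutive frames of one clip fall into
different folds this leaks appearance information, which is accepted and
noted here.

## Numerical choices and degenerate inputs

* Channel split `round(alpha C)` with ties up; a split that would leave
  an empty group while `0 < alpha < 1` is a validation error.
* `alpha = 0` collapses every octave operation onto its H→H path; the
  forward pass is then bit-identical to the plain single-stream blocks
  with the same weights (asserted in the tests).
* NMS is class-agnostic, IoU threshold 0.65, ties broken by original
  index; score threshold 0.001 for evaluation, 0.25 for reporting.
* Empty frames contribute only the objectness term; a batch with zero
  positives is flagged and the normaliser floors at one.
* Boxes are half-open pixel rectangles with the origin at the top left;
  conversion to the (x, y, w, h) annotation form is exact.
* Non-finite losses or logits abort with a diagnostic rather than
  propagate.

## Known limitations

Accuracy figures against the in-vivo dataset cannot be checked here (the
data are available only on request); the package substitutes structural
and behavioural checks as described. The engine targets one CPU core;
there is no GPU path and no attempt at multi-threading. Checkpoints are
RDS containers tied to the module registration order of the building
code. Three published complexity figures deviate as documented above.
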