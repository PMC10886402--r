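---
title: "Methods: segmentation, morphometrics and weight regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, morphometrics and weight regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and of the design
choices that were genuinely open; it states no empirical result that the
test suite does not itself compute.

## The problem

Breast-muscle (pectoral) weight is a key production trait in broilers.
Measuring it directly requires slaughter; the pipeline implemented here
estimates it in vivo from a radiograph plus the bird's live weight, in three
stages: segment the pectoral muscle, measure its shape, regress grams on
shape + live weight.

## Segmentation network

`maefnet()` assembles a two-class encoder–decoder segmenter.

**Encoder.** A MobileNetV3-Large inverted-residual stack, truncated so the
deepest feature map is at output stride 16: frequent downsampling loses the
local detail that matters for thin muscle boundaries, so the stride-32 stage
and the classification tail are removed. Multistage taps are taken at
strides 4, 8 and 16 (24/40/112 channels). The exact truncation point was the
open design question; the governing constraint is the 1.51 M trainable
parameter budget of the lightweight design. Keeping the first stride-32
block (with its stride forced to 1) overruns that budget once the decoder is
attached (≈ 1.6 M), so the encoder ends at the last 112-channel block and
the budget holds with ≈ 1.12 M parameters. The deepest tap is then natively
at stride 16 and nothing needs a forced stride. Grayscale input is
replicated to three channels so the standard stem is reused; the network is
always trained from scratch.

**Decoder.** Per tap, an Attention Refinement Module (ARM) reduces channels
with a 3×3 conv + BN + ReLU and gates them with sigmoid channel weights
derived from global average pooling; a Coordinate Attention Module (CAM)
follows each ARM, gating with direction-aware weights from height- and
width-wise average pools (bottleneck ratio r = 16, minimum 8 internal
channels). The three branches (ARM widths 32/64/128 shallow→deep) are fused
coarse-to-fine by two Feature Fusion Modules (concatenate, 3×3 reduce,
squeeze-excite-style additive gate; widths 64 then 32), followed by a 1×1
two-class head and a 4× bilinear upsample. In the published formulation the
attention weights of the CAM are printed with the same symbol that denotes
ReLU elsewhere; multiplicative gating requires weights in (0, 1), so sigmoid
is used for every attention weight. ARM/CAM are applied to all three taps.
Decoder widths are configurable; the defaults were chosen to sit inside the
parameter budget.

**Numerical realisation.** Tensors are stored as (N·H·W)×C matrices;
convolutions run as im2col + GEMM (OpenBLAS), depthwise convolutions,
bilinear resampling and the batch-norm/activation inner loops as dedicated
C++ kernels, and every layer carries a hand-written backward pass (verified
against central finite differences in the test suite). Batch normalisation
uses joint batch statistics in training (momentum 0.1, eps 1e-5).

## Training protocol

`train_config()` defaults to the published protocol: 100 epochs, batch
size 8, SGD with constant learning rate 0.01, momentum 0.9, weight decay
1e-4 (a schedule is not specified in the protocol, so the rate is constant).
Cross-entropy in nats guides training (probabilities clamped at 1e-12);
validation reports the dice loss of hard argmax masks — soft dice is not
used, matching the set formulation — plus precision, recall, IoU and DSC.
Aggregation over images is micro (pooled pixel counts) with macro also
reported, since the published choice is unstated. The checkpoint with the
best validation IoU is retained.

Two standard initialisation/regularisation conventions are adopted where
the protocol is silent: weight decay applies to convolution weights only
(batch-norm gains/offsets and biases are excluded), and the projection
batch-norm gain of every skip-connected inverted-residual block starts at
zero so each such block begins as an identity map. Both are common practice
in modern CNN training and materially speed convergence at small step
counts.

One choice needs explanation: after training, batch-norm moving averages are
replaced by exact statistics recomputed over the training split
("precise BN", `refresh_bn_stats()`). The moving averages are an EMA along a
drifting weight trajectory; at desk-scale step counts (tens to hundreds of
updates) they lag the final weights badly enough to cost tens of IoU points
in evaluation mode while train-mode predictions are already near-perfect.
The refresh removes the train/eval discrepancy without touching the
learning dynamics.

Zero-denominator conventions (degenerate masks never arise in practice but
must be defined): empty∧empty dice loss is 0; all-zero confusion counts give
100 % metrics; a zero denominator inside precision/recall with nonzero
errors gives 0.

## Shape morphometrics

`extract_geometry()` measures the largest 8-connected component (predicted
masks may carry specks): pixel count A; convex-hull pixel count Ca
(hull of pixel centres, rasterized with the same centre-inside rule as the
polygon rasterizer); perimeter P, by default the polygonal chain length of
the outer Moore contour (axial steps 1, diagonal steps √2 — the contour arc
length an OpenCV-based pipeline reports). The literal boundary-pixel count
(foreground pixels with a 4-neighbour background, border counting as
background) is available as `perimeter = "pixel"`, but it was measured to
underestimate a smooth circle's perimeter by ≈ 10 % (digital disk r = 50:
Heywood factor 0.891), which breaks the analytic identity Hcf ≈ 1 that the
descriptor is defined by — hence the chain length is the default. Interior
holes, which do not arise for the star-shaped phantom regions, are ignored
by the chain tracer; moment-ellipse axes
(4√λ of the second-central-moment eigenvalues); tight bounding box H×W; and
the diameter D of the minimum enclosing circle of the pixel centres (Welzl's
algorithm on the hull). The alternative reading of D — twice the
centroid-to-farthest-edge distance — is exposed via
`extract_geometry(..., diameter = "centroid")`; the circumscribed circle is
the default. The 15 descriptors follow the standard formulas; the Heywood
circularity factor is P/(2·√(π·A)), which equals 1 for an ideal disk.

## Weight regression

Candidates are live weight plus the 15 descriptors. Features are z-scored
(scaler fit on training rows only; the target stays in grams so ε = 0.3 g
keeps its physical meaning — whether the original work scaled anything is
unstated, and this is the only scaling under which its stated C and ε are
meaningful across features of very different magnitudes). RFE ranks features
by the absolute coefficients of the linear SVR refit after each removal
(ties: the later column is removed first), and the subset size is chosen by
5-fold cross-validated mean R²; this reading reconciles the published
description of per-step elimination with subset-level scoring by R². Fold
assignment is a seeded uniform shuffle without stratification (continuous
target). The pipeline stores whatever subset wins — nothing is hard-coded.

## The phantom generator

Phantoms stand in for the private radiograph data: a bright elliptical body
silhouette (grey level 140) on dark background (30), a smoother muscle blob
(+45) whose exact pixel set is the ground-truth mask, and Gaussian sensor
noise (σ = 8 grey levels). The muscle contour is an ellipse with 3–5
low-frequency radial harmonics (total amplitude ≤ 15 % of the radius), which
keeps the region star-shaped — hence a single connected component — while
exercising the convexity/circularity descriptors non-trivially. Muscle area
fraction (4–22 % of the canvas) rises with live weight plus jitter, so
feature selection faces correlated candidates as in real birds. Live weight
is uniform on 1800–3200 g (market-age broilers) and
`bmw = 60 + 0.12·LW + 0.004·A + N(0, 10 g)` at the default 512-px canvas,
landing breast-muscle weights in roughly 300–800 g, the range reported for
100-bird cohorts of this kind. Two caveats are deliberate: the phantoms make
no claim of radiographic realism (no skeleton, no attenuation physics, one
canonical pose), and the intensity statistics of real scanners are unknown —
so passing tests demonstrate that the pipeline recovers known ground truth,
not that it reaches any particular accuracy on real radiographs, whose
published headline numbers (IoU ≈ 96 %, R² ≈ 0.88) are not reproducible
without the private data.

A note on feature recovery: the generative weight relation is affine in raw
area A, while the candidate set encodes area only through monotone
transforms (√A and its relatives). Over the configured area range the best
linear combination of those transforms captures A to well under 1 % residual
variance, which is why the noise-free recovery requirement (CV R² ≥ 0.99)
is attainable; the recovery test accordingly accepts any of Ar/Co/Ed as the
"area" member of the selected subset, alongside live weight.

## Problem sizes used by the test suite

Chosen as the package's own desk-scale study conditions: segmentation
convergence uses 200 phantoms at 128 px (7:2:1 split) for 30 epochs and an
overfit sanity run of 8 phantoms for 50 epochs; weight-model recovery uses
100 noise-free phantoms at the default 512 px; the rasterization oracle
sweeps 100 random polygons on ≤32×32 grids; determinism checks regenerate
datasets and retrain small models twice. Training at these sizes is minutes,
not hours, on a single CPU core.

## Known limitations

- No DICOM input, multi-class annotation, or automatic crop detection; crop
  boxes are user-supplied (the published pipeline does not state its crop
  coordinates).
- The CAM's sigmoid-vs-ReLU ambiguity and the exact encoder truncation are
  resolved by design arguments (gating range; parameter budget) rather than
  by a published table of layer shapes.
- Single-threaded by design for bitwise reproducibility; the kernels lean on
  BLAS for throughput.
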