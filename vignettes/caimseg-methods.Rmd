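---
title: "caimseg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{caimseg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Two-photon Ca2+ imaging records the activity of hundreds of neurons as a
movie of a field of view. Downstream analysis needs the pixel mask of
every soma. Manual annotation is the accuracy reference but does not
scale, and the two obvious 2D summaries of a movie each miss neurons:
the *average projection* shows anatomy (somata appear as "donuts",
because cytoplasmic indicator leaves the nucleus dark) but hides
sparsely firing cells whose resting fluorescence sits at the background
level, while a *correlation image* highlights active cells but not
quiet ones. caimseg therefore (i) fuses both summaries into one input
image, (ii) segments neurons in that image with a compact instance
segmentation network, and (iii) scores detections against ground truth
with an assignment-based precision/recall/F1 protocol.

## Preprocessing: the fused input image

For every pixel we take the temporal traces $f_i$ of its square
neighbourhood (radius 3 px, i.e. $7\times7$ support) and compute the
Gaussian-weighted multidimensional correlation

$$c_w = \frac{\lVert \sum_i a_i f_i \rVert_2}{\sum_i a_i \lVert f_i \rVert_2},$$

with weights $a_i$ from an isotropic Gaussian ($\sigma = 1.5$ px)
centred on the pixel. By the triangle inequality $c_w \in [0, 1]$, with
equality when all neighbourhood traces are positively proportional —
which is what coherent Ca2+ transients across a soma produce.

Design choices a user should know about:

* **Trace centring** (`center_traces = TRUE`, default): each pixel's
  temporal mean is subtracted first. Without centring, the shared
  positive baseline makes every trace nearly parallel and $c_w \to 1$
  everywhere; with centring, only genuinely co-fluctuating pixels score
  high. The flag is exposed because the raw-trace variant is also
  meaningful for high-SNR data.
* **Border handling**: the neighbourhood is truncated at image borders.
  No weight renormalisation is needed because the same truncated weight
  sum appears in numerator and denominator.
* **Dead pixels**: if every neighbourhood trace has zero norm the ratio
  is undefined; we define $c_w = 0$ (no evidence of a neuron).
* **Fusion**: the average image and the correlation map are each
  min-max normalised to $[0,1]$ and combined as
  $\alpha\,\mathrm{avg} + (1-\alpha)\,\mathrm{corr}$ with
  $\alpha = 0.5$ by default. The sources describe fusion only
  qualitatively; the convex combination is this package's documented
  choice, with $\alpha$ exposed in `fusion_config()`. A constant input
  normalises to all zeros with a warning.

Annotated benchmark movies are expanded into seven images each
(`split_and_project()`): six from an evenly divided movie plus one from
the whole movie. Remainder frames go to the earliest segments
(`T %% n` segments get one extra frame), a deterministic rule that
keeps the partition order-preserving.

## The detector

`build_model()` instantiates a compact Mask R-CNN-style detector whose
every studied component is a configuration switch, so each ablation arm
is constructible from `model_config()` alone:

* **Backbone**: a residual conv net producing C2–C5 at strides 4–32;
  with `path_augmentation = TRUE` one extra down-sampling stage yields
  C6 at stride 64, turning four feature outputs into five.
* **FPN**: 1×1 lateral projections plus top-down nearest-neighbour
  up-sampling; `fusion_up` selects *add* (default) or *concat* fusion.
* **ECA attention** on every lateral connection
  (`attention = "eca"`): global average pooling to a channel vector, a
  bias-free zero-padded 1D convolution (kernel 3 by default; the
  adaptive channel-dependent rule is available via
  `eca_kernel = "adaptive"`), a logistic gate, and channel-wise
  rescaling. The gate is purely multiplicative, so it adds exactly
  `kernel` weights per lateral connection — a property the tests use to
  predict parameter-count deltas. A CBAM arm (channel + spatial
  attention) exists for comparison only.
* **FPN+** (`fpn_plus = TRUE`): an additional bottom-up path. Y2 starts
  from P2; each higher map is the fusion of a stride-2 convolution of
  the previous Y with a 1×1 lateral projection of the corresponding P
  (`fusion_down`, default *concat*), giving Y2–Y6. Every concatenation
  is followed by a cross-stage partial (CSP) layer — split into two
  half-width 1×1 branches, one passing `csp_depth` bottlenecks, then
  re-merged — which mixes and re-compresses channels. The exact wiring
  of the lateral connections into the new path is under-specified in
  the sources; per-level 1×1 projections of the FPN outputs are this
  package's documented resolution.
* **Heads**: a shared RPN (one square anchor per level, sides from
  `anchor_scales`, default 8–128 px chosen to bracket 10–30 px neuron
  diameters across strides 4–64), ROI-Align with one bilinear sample
  per bin (7×7 for the classification/box head, 14×14 for the mask
  head), a two-layer box head, and a four-convolution mask head
  emitting 28×28 logits.

The training loss is the sum of three nonnegative components —
classification (RPN objectness + ROI softmax), box regression
(smooth-L1 on positive anchors and foreground ROIs), and mask
(per-pixel binary cross-entropy) — and `model_loss()` reports all three
so their bookkeeping identity is testable.

### The compute engine

No deep-learning framework is involved: the package carries its own
minimal reverse-mode autodiff tape (`R/autograd.R`) with Rcpp kernels
for im2col/col2im convolution and ROI-Align. This keeps the entire
computation inspectable and dependency-light, at the price of scale:
the default channel widths (`backbone_depth = "small"`; `"tiny"` for
tests) are far narrower than an ImageNet-scale backbone. The topology —
not the width — is the subject of the architecture switches, and
layer-level gradients are verified against finite differences in the
test suite. Gradients do not flow through proposal box coordinates
(standard practice in this detector family); ROI-Align backpropagates
into the pyramid features.

Numerical choices: He-scaled Gaussian initialisation seeded by
`init_seed` (a config maps to a reproducible model); box-delta
exponentials clamped at $e^{\pm4}$; NMS thresholds 0.7 (proposals) and
0.5 (detections); mask binarisation at 0.5; inputs zero-padded to the
square `input_size`, which must be a multiple of the largest stride.

## Training

`train_model()` runs SGD with momentum 0.9 and weight decay $10^{-4}$
(the convention for this detector family; the sources state only
learning rates), with the global gradient norm clipped at 5 for
stability at small batch sizes. Two published schedules are built in:
`hybrid_schedule()` (50 head-only epochs at $10^{-3}$, then 100
full-network epochs at $2\times10^{-4}$, then 50 at $10^{-4}$; 500
steps/epoch, batch 2) and `neurofinder_schedule()` (20 head-only + 130
full-network epochs at $10^{-3}$; 50 steps/epoch, batch 2). The
"head" scope freezes everything except the ROI classification/box and
mask heads — the RPN is deliberately excluded, matching the convention
of adapting only per-ROI heads when starting from pre-trained features;
the exact layer boundary is not defined in the sources, so this scope
is documented as the package's choice. Frozen parameters are untouched
to the bit, an invariant the tests assert.

`cross_validate()` implements both protocols: *two-round hybrid* (each
half's model trains on the union of the other half's training data and
is tested on that half's test items, so every group is tested exactly
once by a model that never saw it) and *round-per-group single*
cross-validation. Sample identities are tracked so leakage is testable.

Augmentation (`augment_pair()`) draws $k \sim U\{0..5\}$ distinct
operations from {horizontal flip, vertical flip, rotation by 90/180/270
degrees, scaling by 0.8–1.5, Gaussian noise with $\sigma \in [0,5]$ on
the 0–255 scale} and applies them in a fixed canonical order (geometric
before noise) to image and masks jointly; noise touches the image only.
The sources do not state an application order or whether the noise
intensity refers to the 8-bit scale; both resolutions are documented
here. Mask resampling uses nearest-neighbour so labels stay crisp;
scaled images are padded/cropped back to the original canvas.

## Evaluation

Masks are matched by minimum-cost assignment (Hungarian algorithm,
implemented as shortest augmenting paths and cross-checked in the tests
against both a brute-force permutation oracle and an independent
solver). The pair cost is $1-\mathrm{IoU}$ when $\mathrm{IoU} \ge 0.5$
*or* when one mask contains the other, and infinite otherwise; the
disjunctive reading is the only one in which the containment clause is
not redundant, and it admits concentric pairs (a detection covering a
neuron's bright core) that the IoU threshold alone would reject.
Infinite entries are replaced inside the solver by a sentinel larger
than $n \times$ the largest finite cost — provably never displacing an
all-finite assignment — and sentinel pairs are discarded afterwards.
Matched pairs are the true positives;
$\mathrm{recall}=N_{TP}/N_{GT}$,
$\mathrm{precision}=N_{TP}/N_{det}$, and F1 is their harmonic mean,
with the conservative zero conventions for empty denominators. Reports
print at 4 decimal places.

## Tiling

Mesoscopic fields (e.g. $1{,}682 \times 1{,}792$ px) exceed the network
input, so `make_grid()` covers the image with
$\lceil H/s\rceil \times \lceil W/s\rceil$ tiles
($s = \text{tile} - \text{overlap}$), border tiles clipped. The default
100 px tile with no overlap reproduces the published 306-tile count for
that field size; for actual inference an overlap of ~20 px (one neuron
diameter) is recommended so no neuron is split in every tile that sees
it — the sources do not describe their handling of border-spanning
neurons, and overlap-plus-merge is this package's resolution.
`merge_tiles()` translates detections to global coordinates and
collapses cross-tile duplicates (IoU ≥ 0.5) by pixel union, keeping the
higher score, iterated to a fixed point so merging is idempotent.

## The synthetic-data generator

`generate_scene()` emulates exactly the structure the method exploits,
with all study conditions fixed as defaults: a 128×128 px field, 300
frames at 10 Hz, 12 neurons of radius 6–10 px rendered as
Gaussian-smoothed annuli (hole at 0.25 of ring intensity, blur
$\sigma = 1$ px to avoid aliasing), 50% active neurons with 0.2 Hz
Poisson transients decaying with $\tau = 10$ frames and amplitude 0.5,
baselines 0.25–0.45 over a 0.2 background, additive Gaussian noise
$\sigma = 0.05$, and one deliberately overlapping neuron pair placed by
rejection sampling (non-pair somata keep ≥ 3 px clearance). One active
neuron is designated *sparse*: its baseline is zero (resting
fluorescence equals the background) and its event count is clamped to
1–2, so it is invisible in the average projection (mask-to-background
contrast < 1.2) yet clearly visible in the correlation map (contrast
> 1.5) in every realisation — the phenomenon that motivates image
fusion, asserted numerically in the tests. Traces come from
`generate_transients()`, a Poisson-events-times-exponential-kernel
model.

What the generator does **not** emulate: neuropil contamination,
photobleaching, motion artifacts, spatially correlated noise, and
realistic soma morphology variation. Passing tests on synthetic scenes
therefore demonstrate that the pipeline's machinery is correct and
trainable end-to-end, not that the shipped defaults reach benchmark
accuracy on real recordings — that requires training at realistic scale
on annotated data.

## Problem sizes in tests and the acceptance script

The test suite and `scripts/acceptance.R` exercise the full pipeline at
desk scale, the package's chosen trade-off between coverage and
turnaround: 96×96 px scenes with 80 frames and 5 neurons for training
checks, the `"tiny"` backbone at 128 px input, and a 400-step
single-scene overfit whose detector must recover its own neurons with
F1 > 0.8 (it reaches 1.0). Training descent is checked on a two-image
set (50 steps), and gradient correctness by central finite differences
at randomly sampled coordinates. Published benchmark averages (e.g.
F1 ≈ 0.64 on the community benchmark) are *not* reproduced here: they
require GPU-scale training on external data, which is out of scope.

## Known limitations

* The engine is CPU-bound R; at published scale (512 px inputs,
  ImageNet-width backbones, 200-epoch schedules) it is impractical.
* A detector overfit on one scene without flip augmentation is not
  flip-equivariant — it memorises the scene in its training
  orientation. Approximate equivariance is an emergent property of
  training with geometric augmentation at scale, not of the
  architecture, so it is not asserted in the test suite.
* One anchor per pyramid level (square, one aspect ratio) — adequate
  for round somata, not for elongated structures.
* HDF5 containers are not read; videos travel as multi-page TIFF (with
  a JSON range sidecar for arbitrary-unit intensities).
* `two_round_hybrid` requires an even group count; the published
  description of the second round is ambiguous and the implemented
  contract (train on the other half, test on your own half) is stated
  in `?cross_validate`.
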