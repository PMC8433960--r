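---
title: "Dissimilarity-space classification with Siamese networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissimilarity-space classification with Siamese networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siamdiss)
```

## The model

Instead of classifying images in a raw feature space, `siamdiss` re-represents
each image by its *dissimilarities to a fixed set of prototypes*. The pipeline
has four stages:

1. **Prototypes.** k-means on the flattened training pixels produces k
   centroids, reshaped back into images. A sample is later described by its
   k distances to these prototypes, so k is the dimension of the learned
   representation.
2. **Metric learning.** A Siamese network — one small CNN backbone shared by
   both branches, joined by a head `sigmoid(affine(|F1 - F2|))` — learns a
   dissimilarity measure between image pairs. Two objectives are provided:
   binary cross-entropy on pair targets, and a clipped triplet objective
   (below).
3. **Dissimilarity spaces.** Each image becomes a k-vector of
   pattern–prototype dissimilarities, by one of two constructions:
   * **FULLY**: the head output itself, `d(x, p) = head(x, p)`, entries in
     (0, 1);
   * **DEEPER**: activations of a tapped deeper convolutional layer are
     compressed per channel to the 9 × 9 low-frequency block of the
     orthonormal 2-D DCT, concatenated (81·C′ values), and compared by
     cosine distance, entries in [0, 2].
4. **Classification and fusion.** An RBF SVM (C = 1000, γ = 0.1, no
   hyperparameter search) is trained on each dissimilarity space; one space
   (and one freshly trained network) per prototype count k. The per-member
   class scores are fused by the average rule; scores from an external
   classifier can additionally be standardized to global mean 0 / sd 1 and
   fused by the sum rule (`fuse_with_external()`).

The training convention deserves emphasis, because the two natural readings
of a Siamese head conflict: the head could predict *similarity* (probability
of same class) or *dissimilarity*. `siamdiss` trains with **pair target 1 =
different-class pair**, so the head output *is* the dissimilarity and feeds
the FULLY space directly, monotone in "more dissimilar". With the opposite
convention every FULLY entry would need flipping; nothing else would change.

### The triplet objective

For anchor/positive/negative embeddings squashed element-wise by a sigmoid
(YA, YP, YN), the per-triplet loss is

    L = max( ||YA - YP||^2 - ||YA - YN||^2 , -margin )

with margin 1 by default. Note the **clip at −margin** instead of the
conventional hinge `max(d_ap − d_an + margin, 0)`: the objective is negative
once the negative is farther than the positive and keeps improving until the
gap reaches the margin, at which point the gradient is exactly zero (clipped
rows contribute nothing). The conventional hinge is available via
`triplet_loss(..., variant = "hinge")` for comparison but is never the
default, because the clipped form is the definition this system is built
around. Whether the norm is squared is a genuine ambiguity; the squared form
is implemented, and no non-squared variant is exposed.

### The optimizers

Three update rules share Adam's moment bookkeeping (decay rates ρ₁ = 0.9,
ρ₂ = 0.99, ε = 1e−8, bias correction with step counter t starting at 1):

* **Adam** — `θ ← θ − λ·m̂/(√û + ε)`.
* **DGrad** — the Adam step is scaled element-wise by
  `ξ = Sig(4·Δaĝ)`, where `Δag = |g − avg|` is the deviation of the current
  gradient from a moving average `avg`, normalized by its maximum over the
  parameter tensor. Components with no deviation get ξ = 0.5; the maximal
  component gets Sig(4) ≈ 0.982, so a DGrad step is always strictly smaller
  than the Adam step.
* **DecayDGrad** — DGrad's ξ is further multiplied by a periodic impulse
  `imp_t = exp(−(2·(t mod s)/s)²)` (period s = 10; maximum 1 at multiples of
  s) and a global bell-shaped decay `d_t = exp(−2(t − c·niter)²/niter²)`
  peaking at the fraction c = 0.25 of the planned iterations. The product
  keeps the effective rate high early and attenuates it within each
  s-iteration span and globally toward the end.

Three definitional choices were open and are fixed as follows, as this
package's own conventions:

* `avg` tracks the moving average of the **element-wise squared** gradients
  (decay ρ₂, `avg₀ = 0`) — the literal definition, even though it mixes the
  scale of g and g². An alternate mode tracking raw gradients exists behind
  `optimizer_state(avg_mode = "grad")`.
* The normalization maximum `max(Δag)` is taken **per parameter tensor**
  (per conv weight array, per bias vector), matching how framework
  optimizers partition state. A tensor whose deviations are all zero uses
  `Δaĝ = 0` (hence ξ = 0.5), the only finite continuous completion of 0/0.
* One counter t (counting optimizer updates from 1) drives bias correction
  *and* the imp/d factors. The origin of the schedule counter is not
  otherwise constrained; this choice makes the first update t = 1.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `ks` | 15, 30, 45, 60 | prototype counts; one network + SVM per k |
| `iterations` | 3000 | optimizer updates (no stop criterion) |
| `lr` | 1e−4 | learning rate λ |
| `batch_size` | 32 | pairs/triplets per update (not externally constrained; 32 is ordinary minibatch practice) |
| `margin` | 1 | triplet clip bound |
| `s`, `c` | 10, 0.25 | impulse period, decay-center fraction |
| SVM `cost`, `gamma` | 1000, 0.1 | fixed generic RBF setting, deliberately untuned |

"Iteration" means one optimizer update on one minibatch; pairs are drawn
balanced (half same-class, half different-class) fresh at every iteration
rather than enumerating every pair of the training set, which is quadratic.
`sample_pairs(..., exhaustive = TRUE)` provides the exhaustive enumeration
for small data.

## Prototype clustering choices

Clustering runs in **raw pixel space** by default. A feature-space
alternative exists (`compute_prototypes(features = ...)`), but FULLY is only
defined when prototypes are images that can be pushed through the network,
so pixel space is the default that serves both constructions with a single
clustering per k. k-means uses k-means++ seeding, 5 restarts (best
within-cluster sum of squares kept), Lloyd iterations capped at 300 — robust
defaults chosen once for determinism and reproducibility, not tuned. A
supervised per-class mode (`per_class = TRUE`, k/n_classes centroids per
class, remainder to the largest classes) is provided as a configuration
switch; the default remains unsupervised since the supervised variant's
exact construction is not externally pinned down.

When k equals the number of distinct training images the clustering
degenerates gracefully: every distinct image is its own centroid and the
inertia is exactly zero.

## DCT conventions

`dct2` is the standard **orthonormal type-II** transform in matrix form
(`C X Cᵀ`), which is energy-preserving and exactly invertible — the
properties (energy compaction into the low-frequency corner) that justify
keeping only the top-left 9 × 9 block. The test suite pins the
implementation against a brute-force O(N⁴) double-sum evaluation of the same
orthonormal form. Coefficient selection is the contiguous top-left block
rather than a zig-zag scan, for simplicity; non-square tap layers are
center-cropped to square before the transform; channels smaller than 9 × 9
contribute their full coefficient block zero-padded to 81 entries, keeping
descriptor length at exactly 81·C′ for any geometry.

The default tap layer is the deepest convolutional map (the layer feeding
the last rectifier), a deep-but-not-final representation chosen to avoid
tying the descriptor to the embedding that the loss directly shapes.

## The backbone and its engine

No deep-learning framework is assumed: the package carries a compact CNN
engine (conv/max-pool/rectifier/fully-connected with exact hand-derived
backward passes, verified against central differences in the tests).
Backbones are described declaratively by `backbone_spec()` and serialize to
JSON, so alternative topologies can be supplied as config files. The default
is three 3 × 3 conv blocks (8, 16, 32 channels) with 2 × 2 max pooling and a
64-dimensional embedding — small enough to train on a CPU in seconds per
hundred iterations on 32 × 32 inputs. Initialization is seeded He-style
fan-in uniform; biases start at zero. Weight tying is structural: there is
exactly one parameter set, and both branches' gradients are summed into it.

Numerical edge rules, all deliberate:

* BCE predictions are clamped 1e−7 from the boundaries to keep the loss
  finite; gradients use the unclamped logistic identity `(y − t)`.
* `|F1 − F2|` uses subgradient 0 at 0 (an exact tie contributes nothing).
* Max-pool ties route the gradient to the first window position in
  row-major order.
* Cosine distance of an all-zero vector is defined as 1 (maximal
  ignorance); zero descriptors arise naturally from zero activations.
* Argmax ties in classification break toward the lowest class index.

## The synthetic generator

`generate_toy_dataset()` makes class-structured texture images: each class
is an oriented sinusoidal grating (orientation and frequency are functions
of the class index) plus a Gaussian intensity blob at a class-specific
position, with i.i.d. Gaussian pixel noise (default sd 0.05 on the [0, 1]
scale) and clipping. Patterns are deterministic in (class, seed) under R's
Mersenne-Twister RNG, and single-channel patterns are replicated to three
bands so the whole pipeline can assume C = 3 (mirroring the usual
band-replication treatment of grayscale inputs).

The generator emulates what the pipeline needs from real data — consistent
within-class structure, distinct between-class structure, pixel noise — and
nothing else: no illumination or pose variation, no class imbalance, no
label noise, no correlated (e.g. patient-level) grouping between train and
test. Green tests on this data demonstrate that the machinery is correct
and that the representation separates genuinely distinct textures; they do
not predict accuracy on real bioimage or spectrogram collections.

Tests and the acceptance script run deliberately small problem sizes chosen
as this package's own test conditions: 3 classes of 32 × 32 images, 60
training and 30 held-out samples, k ∈ {3, 5}, 300 iterations, batch 16,
five seeds for the recovery check and 50 iterations per cell for the
loss × space × optimizer grid. At these sizes a full recovery run completes
in well under ten minutes on one CPU, and the fused FULLY ensemble recovers
the held-out classes at ≥ 0.90 accuracy for at least four of five seeds.

## Preprocessing hook

Handcrafted-descriptor preprocessing (such as covariance-based descriptor
images) is out of scope as a computation, but `read_image_dir()` exposes a
per-image `preprocess` hook (identity by default) so a descriptor transform
can be plugged in at load time; the pipeline is agnostic to what the three
channels contain.

## Known limitations

* The engine is CPU-only and meant for small backbones and images (tens of
  pixels); it is an exercise in correctness, not throughput.
* Only PNG images are read from class-folder directories.
* Cross-validation protocols are not built in; callers supply explicit
  train/test splits (`split_dataset()` or separate folders), which keeps
  per-dataset protocol decisions out of the engine.
* The SVM score aggregation uses signed one-vs-one decision-value votes,
  not calibrated probabilities; a probability mode can be layered on via
  `e1071` if calibrated outputs are ever needed.
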