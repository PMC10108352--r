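---
title: "Latent healing: model, design choices, and what the synthetic benchmark shows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent healing: model, design choices, and what the synthetic benchmark shows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentheal)
```

## The model

latentheal detects and segments anomalies in brain-like images without ever
seeing an anomalous training example. Three components cooperate:

**A vector-quantized autoencoder** compresses the image into a grid of
discrete tokens. The image is cut into non-overlapping `f x f` patches
(`f = 8` by default, so a 64x64 image becomes an 8x8 token grid); each patch
is embedded, snapped to the nearest of `K = 32` learned codebook vectors
(squared Euclidean distance, ties broken toward the lowest index for
determinism), and decoded back by a small MLP with a sigmoid output. The
codebook is learned by exponential-moving-average updates (decay 0.99,
Laplace smoothing 1e-5): cluster-size and embedding-sum accumulators decay
toward each batch's assignments, and each codebook vector is the smoothed
sum over the Laplace-smoothed size. The training objective is the per-pixel
mean squared reconstruction error plus `beta = 0.25` times the commitment
term (the squared distance between encodings and their assigned, detached
codebook vectors); the codebook loss term is replaced by the EMA update.
Gradients pass through the quantizer by the straight-through convention (the
quantizer is treated as the identity in the backward pass), and a per-pixel
mean reduction keeps the loss scale independent of image size.

**Why the encoder is anchored to pixel space.** The encoder is a residual
map `z = P + MLP(P)` whose learned part is *disabled by default*
(`encoder_warp = FALSE`, so `z = P` exactly and the codebook is learned as
online k-means over patches). This is a deliberate design decision, made
after observing the alternative fail in a specific, instructive way: when
the warp is trained, the commitment term contracts the encoding space toward
the codebook, and at test time this contraction generalizes to patches the
model has never seen — precisely the anomalous ones. Anomalous patches then
land on *common* codes, the latent code looks normal, the density models
cannot flag it, and the resampling mask filters out the very residuals that
carried the anomaly. In other words, the encoder itself "heals" the anomaly
before the density model can see it, and the segmentation degrades. With
the identity embedding, an out-of-distribution patch keeps its
out-of-distribution code assignment, the mask recovers it, and the
mask-filtering stage improves rather than degrades segmentation. The warp
remains available (`encoder_warp = TRUE`) and its gradient path, including
the straight-through contract, is exercised by the unit tests.

**An autoregressive density over token sequences.** A fixed ordering
(raster, S-curve, generalized Hilbert, or a seeded random permutation) turns
the token grid into a 1D sequence. For each ordering we train an independent
density model for `p(s) = prod_i p(s_i | s_<i)`. The model is a back-off
categorical estimator: the context of position `i` is the token values of
the grid cells adjacent to cell `i` that were *already visited* by the
ordering (for a raster scan: the cells to the left and above — the same
information a convolutional autoregressive image model would see). The
conditional interpolates, by recursive Dirichlet smoothing with strength
`alpha = 1`, between the (position, full context) counts, the
(position, nearest-neighbour) counts, the positional counts, the global
token frequencies, and the uniform distribution. Every level is estimated in
closed form by counting, which makes training exact maximum likelihood
(minimizing the mean sequence negative log-likelihood), deterministic, and
fast; an untrained model is exactly uniform, and causality is structural
because all context positions precede `i`. The choice of a count-based
estimator over a neural sequence model is an explicit design decision for
this package: at the latent sizes the package targets (64–4096 tokens,
K ≤ 64), the graph-structured context captures the same neighbourhood
information, fits in seconds on one CPU core, and gives reproducible
likelihoods; the interface (teacher-forced per-position distributions,
sequence likelihoods, ancestral sampling with temperature) is agnostic to
the estimator behind it.

**Healing and masked residuals.** Token likelihoods are computed in one
teacher-forced pass over the *original* sequence; tokens with
`p(s_i) <= threshold` form the resampling mask (threshold 0.005 in 2D,
0.001 in 3D — likelihood scales shrink with sequence length, hence the
smaller 3D value). Masked tokens are resampled left to right conditioned on
the already-healed prefix, in a single pass (no iteration to convergence,
and no re-scoring of likelihoods after partial healing — the mask is fixed
up front). The healed grid is decoded; the residual `|x - x̂'|` (or its
positive part `max(x - x̂', 0)` when anomalies are known to be
hyperintense) is multiplied by the resampling mask mapped back to image
space: inverse ordering, nearest-neighbour upsampling of each latent cell to
its `f x f` patch, Gaussian smoothing with `sigma = f/2` pixels, clipping to
[0, 1]. Smoothing softens the blocky latent-resolution mask so residual
evidence near mask borders is attenuated rather than cut; mirror-padded
convolution keeps the all-ones and all-zero masks exact. Each ensemble
member applies *its own* mask before the ensemble mean, since each member
owns its own resampling decisions.

**Image-wise detection.** `log p(x) = sum_i log p(s_i)` per member, averaged
over the ensemble. For the two-feature variant, the lesion volume is counted
from the ensemble residual binarized at a threshold chosen on normal
validation images as the upper 0.1% quantile of their residual values (when
validation ground truth exists, the DICE-maximizing threshold is the
alternative rule). Both features are standardized — means and standard
deviations from the validation set — before fitting a one-class SVM (RBF
kernel, `nu = 0.1`, `gamma = 1/2`); higher decision scores mean "more
normal". Standardization matters because raw lesion volumes are orders of
magnitude larger than log-likelihood differences.

## Orderings and the ensemble

An ordering is a bijection between grid cells and sequence positions,
serialized by its descriptor (class, shape, reflections, axis permutation,
seed), never by the raw permutation. The 2D ensemble is the 4 reflection
patterns crossed with transposition (8 orderings); in 3D we use the identity
plus the 6 single- and double-axis reflections (7 orderings, no axis
permutation, keeping all members in one ordering class). The Hilbert class
uses a generalized construction valid for arbitrary rectangles (latent grids
are rarely powers of two); in 3D the curve stacks per-layer 2D curves
boustrophedon, which preserves unit steps between consecutive positions.
One locality note: the *mean* sequence distance between grid-adjacent cells
does not favour Hilbert over raster (the mean is dominated by the few long
jumps every space-filling curve must make); the median distance and the
fraction of unit steps do, and those are the properties the tests assert.

Different orderings expose different already-visited neighbourhoods as
context, so members make decorrelated mistakes; averaging their masked
residuals is what the ensemble contributes.

## The synthetic benchmark

The generator emulates a controlled 2D study design: head-like phantoms
(a bright elliptical skull ring, a mid-gray interior with low-frequency
texture, 1–3 dark ventricle-like blobs, exact-zero background) whose
position, axes, orientation and texture vary by seed; and binary sprite
anomalies (ellipse, rectangle, or region-grown blob; 2–15% of the image
area by default — the sprite-size distribution is a free parameter exposed
in the generator since no canonical value exists) composited with intensity
0 or 1, optionally with additive Gaussian noise (sd 0.2) on the sprite
pixels, and required to overlap the head region by at least 50% (up to 20
placement retries). Far-out-of-distribution fixtures are uniform-noise
images and multi-lobe ("hand-like") shapes. 2D images are min-max scaled to
[0, 1]; 3D volumes use 1st/99th-percentile scaling with clipping.

What it does *not* emulate: acquisition physics, registration error,
partial-volume effects, anatomical covariance between regions, or lesion
textures — sprites are flat-intensity shapes. Passing the benchmark
therefore shows the pipeline's machinery (quantization, likelihood
thresholding, healing, mask filtering, ensembling, metrics) behaves as
designed on images with realistic gross structure; it does not certify
performance on clinical data, which additionally needs the preprocessing
steps (registration, inpainting of training-set lesions) that are outside
this package's scope.

Problem sizes were chosen so the full study runs in a few minutes on one
core: 500 training phantoms of 64x64 (8x8 latent grid), a 4-member raster
ensemble, 50 contaminated test images, and 50/50/60 clean, noise and
validation images for detection. At these sizes the stage-wise ablation of
best-achievable DICE (raw reconstruction residual, healed residual, masked
residual, ensemble) reproduces the expected strictly-improving trend, the
far-OOD detection problem is solved essentially perfectly, and near-OOD
detection improves further when lesion volume joins the log-likelihood
feature — the same directions reported at full scale on real data by the
literature this design follows.

## Numerical conventions and degenerate inputs

- DICE of two empty masks is 1 (perfect agreement); the best-DICE threshold
  search uses *one global threshold* over the pooled test set, with all
  unique residual values as candidates up to 10^4 values and 1024
  quantile-spaced candidates beyond that (the max over a finer grid can
  only grow, which the tests assert).
- Binarization is strictly greater-than, so threshold 0 marks every
  positive residual.
- AUROC uses the rank (tie-aware) formulation — invariant under monotone
  transforms, 0.5 for constant scores; AUPRC is step-interpolated over
  distinct thresholds; FPR-at-TPR takes in-distribution examples as
  positives and reports the anomalous acceptance rate at the tightest score
  cutoff reaching the requested TPR. All metrics refuse degenerate
  (single-class) label sets rather than returning NaN.
- Quantization ties break toward the lowest codebook index; every stochastic
  step (phantom and sprite generation, placement retries, batching,
  initialization, healing draws) consumes an explicit seed and restores the
  caller's RNG state, so every artifact is bit-reproducible from its seeds.
- Likelihood thresholds must lie strictly inside (0, 1); sequences are
  refused when their length or ordering descriptor does not match the model
  they are scored under.

## Known limitations

- The count-based density model backs off to positional statistics for
  contexts never seen in training; extremely heterogeneous training sets
  would dilute those counts. More expressive sequence models can be swapped
  in behind the same interface.
- The patch-based autoencoder reconstructs at patch granularity (one code
  per patch), so residual maps inherit some blockiness; the Gaussian-
  smoothed mask softens but does not remove this.
- Identity encoding gives up learned feature invariances (e.g. to smooth
  intensity gradients); for data where pixel-space distances are a poor
  patch metric, enable the warp and retune.
- The 3D path is implemented and tested at small volume sizes; full-scale
  volumes (hundreds of voxels per side) need longer sequences and more
  memory for the context tables, though both scale linearly in the number
  of cells.
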