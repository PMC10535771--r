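---
title: "Hierarchical extreme learning machines for ultrasound lesion silhouettes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical extreme learning machines for ultrasound lesion silhouettes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helmus)
```

## Scope and assumptions

`helmus` classifies breast ultrasound images into three classes —
benign, malignant, normal — from **mask-derived binary silhouettes**,
not from grayscale echotexture. The working assumption is that each
image comes with a ground-truth lesion boundary (as in the public BUSI
dataset), and that the lesion's *shape* at a coarse 28×28 resolution
carries the class signal: benign lesions tend to have smooth, convex
margins while malignant ones are irregular and spiculated. Images with
an empty mask (no lesion) are, by construction, all-zero silhouettes;
"normal" is therefore trivially separable, and the scientific content
of the classifier lies entirely in the benign/malignant distinction.

This is a deliberate simplification. A silhouette classifier cannot use
echogenicity, posterior acoustic features, or margin texture, and it is
only as good as the segmentation it is given. The package does not
segment lesions from raw grayscale.

## Preprocessing chain

`preprocess_record()` implements the fixed pipeline:

1. **Mask union.** Images can carry several mask files (multi-focal
   lesions); they are merged by pixelwise logical OR. The union is
   commutative, associative, and idempotent, which the test suite
   asserts property-style.
2. **Grayscale binarization.** Mask rasters are thresholded at
   intensity > 127 (the 8-bit midpoint; configurable).
3. **Square sizing.** `center_crop` removes equal margins from the
   longer axis, taking the extra pixel from the trailing edge when the
   margin is odd; `pad` is the symmetric zero-padding alternative. The
   rules are stated exactly so outputs are bit-reproducible.
4. **Block downsampling.** The square raster is reduced to the target
   side (default 28) by area averaging: each output pixel is the
   overlap-weighted mean of the input pixels under its footprint, so
   non-integer scale factors are handled exactly. Block means ≥ 0.5
   map to foreground (ties are foreground, stated to fix bit-exactness).
5. **Flattening.** Row-major, 0-based pixel order, fixed so feature
   vectors are comparable across implementations.

The downsampling rule is verified in the tests against an independent
brute-force overlap integration, and a property test checks that a
centered disk of radius 0.3 × side keeps its analytic area fraction to
within ±20% after a 600 → 28 reduction.

## The single-layer ELM

The decision layer is a classic extreme learning machine: input weights
and biases are drawn i.i.d. uniform on [−1, 1] from a seeded stream and
frozen; only the output weights are learned, by ridge-regularized least
squares on one-hot targets. The solver uses a Cholesky factorization of
`H'H + λI` for λ > 0 and an SVD-based minimum-norm pseudo-inverse for
λ = 0 (rank deficiency is handled, not an error; the rank tolerance is
`max(dim) · eps · σ₁`). Predictions are per-row argmax with ties broken
toward the lowest class index.

Defaults and their reasoning:

| parameter | default | why |
|---|---|---|
| activation | logistic sigmoid | the standard ELM choice; `tanh`, `relu`, `identity` are selectable |
| weight/bias distribution | uniform [−1, 1] | conventional for ELMs; only the seed is tunable |
| ridge λ | 1e−3 | small but nonzero, stabilizing the solve for wide hidden layers |
| hidden nodes | 1000 | the selected operating point of the architecture study |

With at least as many hidden nodes as distinct training samples, a
full-rank activation matrix, and λ = 0, the ELM interpolates its
training targets exactly; the tests assert this together with agreement
(to 1e−8 relative error) with a dense normal-equations oracle.

## The hierarchical ELM

`train_helm()` prepends K unsupervised ELM sparse-autoencoder layers
(default K = 4, read as *four feature layers plus the separate
single-layer decision ELM*; the 3 + 1 reading is available by setting
`n_layers = 3`). Each layer:

1. draws a frozen random projection (uniform [−1, 1]; rows
   orthonormalized when the layer is not wider than its input),
2. min–max normalizes each hidden unit's projection to [−1, 1] before
   the activation — the standard conditioning step for ELM sparse
   autoencoders; without it the design matrix is dominated by a
   constant component and the reconstruction solve is badly
   conditioned,
3. solves the reconstruction problem
   `β = argmin ‖Aβ − H_prev‖² + penalty` and stores `β` as the
   layer's projection; the forward connection is
   `H_i = g(H_{i−1} βᵀ)`.

After the last layer, features are multiplied by a frozen square random
scattering matrix (uniform [−1, 1]; `scatter = "identity"` disables
it) and passed to the decision ELM.

### Numerical choices in the feature stack

**Per-layer rescaling is on by default.** Each layer's output (and the
scattered features) are min–max rescaled per column to [−1, 1], with
the affine parameters stored in the model and replayed at prediction
time. During development the unrescaled sigmoid stack collapsed to
near-constant columns by the second layer (held-out accuracy fell from
≈0.9 to ≈0.6), because sigmoid outputs concentrate near 0.5 and each
reconstruction shrinks the remaining variance. Rescaling restores each
feature's dynamic range; setting `rescale_layers = FALSE` recovers the
raw stack for study.

**The default autoencoder penalty is ridge, not ℓ1.** The ℓ1 path
(monotone FISTA, below) is fully implemented and selectable with
`l1_weight > 0`. It is not the default because, at the package's
standard scale (1000-node layers, sigmoid design matrices), the
soft-threshold level `λ/L` is numerically negligible (~1e−9) while the
fixed-step iteration converges slowly on the ill-conditioned design —
50 iterations leave 15–48% reconstruction error, which compounds across
layers and measurably degrades the features. The closed-form ridge
solve (`ridge_ae = 1e−3`) returns the converged solution directly at a
fraction of the cost; with several hundred FISTA iterations the two
paths agree, which the tests verify on small instances.

**FISTA is the monotone variant.** The ℓ1 solver uses fixed step `1/L`
with `L` the largest eigenvalue of `A'A` (deterministic power iteration
with a 1% safety margin). Plain FISTA's objective can oscillate; the
monotone variant (accept a candidate only if it improves the incumbent,
while the candidate still drives the momentum sequence) guarantees a
non-increasing objective trace, which the tests assert, at the cost of
one extra trace-based objective evaluation per iteration. With an
identity design the first iteration returns the exact soft-threshold
solution.

**Degenerate inputs.** All-identical feature matrices produce a warning
and proceed — the pseudo-inverse handles the rank deficiency. Constant
columns in the min–max normalizations are guarded with an epsilon span.

### Determinism

All randomness flows from one master seed via a documented
stream-splitting rule (`derive_seed(seed, label)`, a small polynomial
hash of the label folded into the seed modulo 2³¹ − 1). Layer `i` uses
stream `"ae<i>"`, the scattering matrix `"scatter"`, the decision map
`"final/map"`, splits `"split/<class>"`. Two runs with one seed produce
byte-identical serialized models (`save_model()` writes all matrices at
full `%.17g` precision in a plain-text container).

## The synthetic benchmark

`generate_dataset()` emulates the silhouettes the preprocessing chain
produces, so the full training pipeline is testable with no download:

* **normal** — all-zero images (an empty mask yields an empty
  silhouette; an optional `speckle` salt-noise rate, off by default,
  makes a harder benchmark);
* **benign** — filled ellipses, semi-axes drawn from 0.15–0.35 of the
  image side, random orientation, random center such that the blob
  fits in the frame;
* **malignant** — star-convex blobs: the ellipse radius function is
  modulated by smooth low-order harmonic boundary noise with amplitude
  drawn from 0.2–0.6 (peak-normalized), plus 4–10 radial spicules.
  Spicule height is its own scale (uniform 0.3–0.7 of the local base
  radius) rather than being tied to the noise amplitude, and spicule
  width is 0.25 rad so that spicules remain resolvable after
  rasterization at the default 28-pixel side.

Shapes are star-convex so membership has a closed form, and a pixel is
foreground iff its center lies inside the analytic shape — both chosen
so the rasterization is checkable by independent scanning oracles. The
generator reproduces the *class geometry* the pipeline assumes, not
real ultrasound: there is no speckle texture, no segmentation error, no
class imbalance (real BUSI is roughly 55/26/17% benign/malignant/
normal), and no intra-observer mask variability. Passing the synthetic
benchmark therefore demonstrates that the pipeline recovers shape-coded
class structure end to end; it does not certify performance on real
clinical data.

The generated set asserts its own invariants: normals are exactly
empty, the perimeter²/area roughness statistic is larger in expectation
for malignant than for benign samples, and identical spec + seed yield
identical bytes.

## Evaluation protocol and problem sizes

`split_dataset()` stratifies by class (per-class seeded shuffle, train
count `floor(fraction · n_class)`); `evaluate()` reports accuracy and
the full confusion matrix (rows = true class); `run_sweep()` re-runs
the experiment over a grid of layer/node counts with derived per-cell
seeds and reports accuracy and wall time per cell. Training time is
reported but never asserted — it is hardware-dependent.

The test suite runs the benchmark at 200 images per class (600 total,
the package's standard size) for the recovery and architecture-trend
checks, and at 6–30 per class for unit-level checks; solver oracles use
instances up to 20×15. These sizes were chosen so the whole suite
completes in a few minutes on one CPU while still exercising the
1000-node default architecture.

## Known limitations

* On the synthetic benchmark at standard size the 4×1000 architecture
  reaches a mean held-out accuracy of roughly 0.90–0.92 depending on
  the seed (see `scripts/acceptance.R` output); the residual errors are
  benign/malignant confusions of weakly-spiculated malignant
  silhouettes. Lesion position, size, and orientation are random
  nuisances, and a random-feature method has no built-in invariance to
  them; at 480 training samples that invariance has to be learned from
  data, which bounds what any of the architectures reaches here.
* The 3-layer and 4-layer architectures perform within about a point
  of each other here; the benefit of the fourth layer reported on real
  BUSI data is not strongly expressed on clean silhouettes.
* The serialized-model container stores dense matrices as text; a
  4×1000 model file is ~100 MB of text. This is deliberate (portable,
  diffable, byte-reproducible) but not compact.
* `scan_dataset()` trusts the BUSI naming convention; files that do
  not match the `<stem>_mask(_k)` pattern are treated as images.
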