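---
title: "Density-map seed counting: model, ground truth, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-map seed counting: model, ground truth, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedcount)
```

## The counting problem

Measuring seed quality indices such as thousand-grain weight requires
counting hundreds of grains per photograph. Segmentation-based counters
fail when grains touch or overlap (conglutinated grains), so this package
takes the density-map route that is standard in crowd counting: learn a
mapping from the image to a nonnegative density surface whose integral
over any region equals the expected number of grains in it. The count of
an image is then simply the sum of its predicted density map, with no
explicit detection or segmentation step, and fractional mass spread over
two touching grains still adds up to two.

## Ground-truth density maps

An annotated image is a set of grain-center points $x_1, \dots, x_N$.
The discrete annotation function $H(x) = \sum_{i=1}^N \delta(x - x_i)$ is
smoothed into a density by convolution with a Gaussian kernel,
$F = H * G_\sigma$. A single fixed $\sigma$ is wrong for photographs that
mix grain shapes, viewing distances and oblique perspectives, so the
bandwidth adapts to local geometry: for each point,
$\bar d_i$ is the mean distance to its $m$ nearest annotated neighbours
and

$$\sigma_i = \beta \, \bar d_i .$$

Densely packed regions (where grains are small or adhering) get narrow
kernels; sparse regions get wide ones. Defaults: $\beta = 0.3$, the value
found to give the cleanest rice density maps; $m = 3$, the smallest
neighbourhood that is robust to annotation jitter (at $m = 1$ a single
duplicated or jittered annotation collapses $\sigma$; at large $m$ the
estimate stops being local).

Two discretization decisions matter and are worth stating precisely:

* **Discrete renormalization.** On a pixel grid with a finite support
  cutoff (`truncation_sigmas`, default 4), a sampled Gaussian does not sum
  to exactly one, and kernels near the border lose mass off the image.
  Each kernel is therefore renormalized to unit sum *after* truncation and
  border clipping. The count is the integral of the map, so exact mass
  conservation outranks pointwise fidelity to the continuous kernel; the
  tests assert $|\,\mathrm{sum}(F) - N\,| \le N \cdot 10^{-6}$.
* **Coordinates.** Points are $(x, y)$ = (column, row), 0-based,
  pixel-center anchored; the annotated pixel receives the kernel peak.
  This convention is enforced in the readers and stated once here.

Degenerate inputs are handled explicitly: an empty annotation list gives
an all-zero map; a single-point image has no neighbour distance, and its
$\sigma$ falls back to `sigma_fixed` when set, else
$\min(0.1 \cdot \min(h, w),\ 15)$ px; coincident duplicate points (zero
neighbour distance) also take the fallback rather than a zero bandwidth.
Nearest-neighbour ties are broken by annotation order, which cannot change
the mean distance.

## The two networks

**MCNN.** Three parallel convolutional columns with large (9×9 leading),
medium (7×7) and small (5×5) receptive fields see the same image; each
column is four convolutions with 2×2 max pools after the first two and
ReLU activations, and a learnable 1×1 convolution fuses the concatenated
column outputs into a one-channel map at 1/4 input resolution. Columns
with larger kernels carry fewer channels (L 16-32-16-8 vs S 24-48-24-12)
so no single scale dominates the parameter budget. Because only the pools
change resolution ('same' padding everywhere) the network accepts any
input whose sides are divisible by 4 — images are never resized, which
would distort the density scale. Training targets are the ground-truth
maps block-sum downsampled ×4, so predicted sums remain counts.

**Improved, prior-guided network.** Counting errors concentrate where
grains adhere. The improved variant attacks this two ways. First, a
*count-level prior branch* — four convolutions (pools after the first
two), spatial pyramid pooling over 1 + 4 + 16 blocks, then three fully
connected layers — classifies the image into one of $M$ coarse count bins
(default $M = 5$, quantile bins over the training counts). SPP makes the
classifier size-agnostic: 21 values per channel regardless of input size,
with floor-boundary blocks that tile the grid exactly. Second, the
density head regresses at *full* resolution: the three (here identical,
7×7/20 → 5×5/40 → 5×5/20 → 5×5/10, PReLU) columns and the prior branch's
last convolutional feature map $C_i$ are concatenated at 1/4 resolution,
passed through two 3×3 fusion convolutions (24, 32 channels), and
upsampled by two stride-2 transposed convolutions (16, 18 channels) plus
a final 1×1 convolution. A terminal ReLU keeps densities nonnegative.

The joint loss is

$$L = \lambda\, L_c + L_d, \qquad
  L_c = -\tfrac1N \sum_i \log \mathrm{softmax}(F_c(X_i))_{y_i}, \qquad
  L_d = \tfrac1N \sum_i \lVert F_d(X_i, C_i) - D_i \rVert^2,$$

with $\lambda = 10^{-4}$ by default. Even at tiny $\lambda$ the prior
shapes the density head, because $C_i$ sits *inside* the regression path:
with $\lambda = 0$ the classifier's fully connected layers receive no
gradient, but the prior convolutions still do, through $C_i$ (this is
asserted by a gradient-probe test).

Architectural details the design left open, and how they were resolved:

* The prior branch consumes the raw image (not an MCNN feature map); this
  keeps the two subtasks' early features independent and makes the
  branch testable in isolation.
* $C_i$ is bilinearly resized to the density trunk's grid before
  concatenation; with the default pooling placement both are already at
  1/4 resolution and the resize is the identity.
* Pools sit after the first two prior convolutions, matching the density
  columns, which is also what aligns $C_i$ with the trunk.
* Transposed convolutions use 2×2 kernels at stride 2, so output blocks
  never overlap and no checkerboard artifact can arise.

## The numerical engine

No deep-learning framework is involved: the package carries a compact
CNN engine (Rcpp/RcppArmadillo) implementing exactly the layers these
two architectures need — im2col + single-precision GEMM convolutions,
2×2 max pooling, SPP, fully connected layers, 2×2-stride-2 transposed
convolutions, ReLU/PReLU, softmax cross-entropy, and SGD-with-momentum
and Adam optimizers. Forward passes and training are deterministic given
the seeds under single-threaded BLAS. Weights start from a centered
normal with sd 0.01 and zero biases (PReLU slopes at 0.25); a
fan-in-scaled initialization was tried and rejected — with a terminal
ReLU it can start the density output in the dead regime, from which
recovery is slow at best.

Optimizer defaults follow crowd-counting practice (SGD, momentum 0.9,
lr $10^{-5}$), but at the desk scales used throughout the tests the Adam
option (`optimizer = "adam"`, lr $10^{-3}$) converges an order of
magnitude faster and is what the worked examples and the acceptance runs
use. A learning rate of $2 \cdot 10^{-3}$ already destabilizes the MCNN,
so $10^{-3}$ is not a conservative choice.

## The synthetic data generator

The generator emulates the structural features of bench-top rice
photographs that matter to a blob-scale counter: three grain shape
classes (elongated, short-oval, long-oval) as rotated filled ellipses
with class-specific axis distributions; a darker split line along the
major axis (rendered as a shading gradient) — the feature that makes
segmentation-based counters split one grain into two; three viewing
conditions (far/near top view as global scale factors 0.75/1.15, oblique
view as a fixed projective warp applied to image and points alike);
controlled grain adhesion (with probability `adhesion_prob` a grain is
placed tangent to or overlapping an earlier one, both flagged); additive
Gaussian noise; and the quarter-area ten-crop augmentation (4 quadrants +
center + 5 seeded random offsets, half-open membership so the quadrants
partition the annotations). Every grain contributes exactly one
annotation at its center, warped together with the image, so annotation
fidelity is exact by construction.

What it does *not* model: texture, specularity, shadows, camera optics,
or full occlusion. Passing tests on this data show that the pipeline is
internally consistent and that the architectures can learn the mapping at
desk scale; they do not certify accuracy on real photographs, whose
appearance variation is far richer.

## Evaluation

Counts are map sums; rounding to whole grains happens only inside the
accuracy metric. Reported metrics are MAE, MSE (the mean of *squared*
errors, not its root — tested against Jensen's inequality
$\mathrm{MSE} \ge \mathrm{MAE}^2$), and the count-ratio accuracy
$\mathrm{ACC} = 100 \cdot \overline{\max(0,\ 1 - |\hat y - y| / y)}$.
A confusion-matrix accuracy is ill-posed for counting — true negatives
are undefined for point detection — so the count-ratio form is the
default single-number ACC, and a detection-level
$\mathrm{TP}/(\mathrm{TP}+\mathrm{FP}+\mathrm{FN})$ (greedy one-to-one
matching of density-map local maxima against truth within a radius) is
available as the secondary, grain-level metric; the adhesion report uses
it to score conglutinated grains specifically. Detection
hyperparameters default to: peak threshold 5% of the per-map maximum,
match radius the image's mean adaptive $\sigma$, NMS separation 2 px.

## Study sizes and reproducibility

All randomness flows from explicit seeds (one per generator sample,
derived as `(rng_seed, index)` streams; one per weight init; one per
training shuffle). The test suite and the acceptance script train on
32 synthetic 96×96 images of 10–30 grains — 100 epochs for the plain
MCNN fitting check (train MAE well under one grain is typical), 120
epochs for the MCNN-vs-improved comparison under heavy adhesion
(`adhesion_prob = 0.6`), where the improved network needs the extra
epochs: it converges more slowly but to better counts, the same
qualitative behaviour reported for the full-scale method. These sizes
were chosen as the smallest at which that behaviour is reproducible;
conclusions at this scale are directional, not estimates of full-scale
accuracy.

## Known limitations

* Parametric ellipse renders cannot probe texture-driven failure modes.
* The improvement margin of the prior-guided network over the MCNN at
  desk scale is seed-dependent; the tests therefore assess the direction
  over three seeds by majority rather than a single margin.
* Training is CPU-bound single-precision; very large images or datasets
  are out of scope.
* The oblique warp is a fixed homography, not a camera model.
* Because the adaptive bandwidth averages over $m$ neighbours, a close
  pair whose other neighbours are distant can receive kernels wide enough
  to merge into one peak; grain-level detection on adaptive ground-truth
  maps therefore has high but not perfect recall (counts, being mass
  integrals, are unaffected).
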